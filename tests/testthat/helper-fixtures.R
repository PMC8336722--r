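# Shared fixtures: tiny phantoms and stacks built in code.

# homogeneous medium phantom, properties in 1/cm
homogeneous_phantom <- function(mua_cm, musp_cm, nz, nx, pitch,
                                wavelengths = 800) {
  nw <- length(wavelengths)
  voxelPhantom(array(mua_cm, c(nz, nx, nw)), array(musp_cm, c(nz, nx, nw)),
               pitch = pitch, wavelengths = wavelengths)
}

# small two-wavelength tube phantom for fast stack tests
tiny_tube_phantom <- function(seed = 7, grid = c(700, 900), pitch = 0.4) {
  cfg <- samplerConfig(nSets = 1L, tubesPerSet = c(2L, 2L),
                       extent = c(16, 10), pitch = pitch,
                       depthRange = c(2, 7), lateralRange = c(-5, 5))
  sampleTrainingVolume(cfg, seed = seed, grid = grid)
}

# fast experiment configuration for pipeline smoke tests
toy_experiment_config <- function(seed = 1, estimators = NULL) {
  if (is.null(estimators))
    estimators <- list(
      estimatorConfig("rf", "milsd", nTrees = 20L),
      estimatorConfig("rf", "lsd", nTrees = 20L),
      estimatorConfig("nn", "milsd", epochs = 3L),
      estimatorConfig("nn", "lsd", epochs = 3L))
  experimentConfig(
    nTrain = 2L, nTest = 2L,
    sampler = samplerConfig(extent = c(16, 10), pitch = 0.4,
                            depthRange = c(2, 7), lateralRange = c(-5, 5)),
    grid = c(700, 900), estimators = estimators, seed = seed)
}

# brute-force percentile by sorting + linear interpolation between order
# statistics (independent of stats::quantile)
brute_force_quantile <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# 2D semi-infinite diffusion Green's function (extrapolated boundary) for a
# pencil beam isotropized at one transport mfp; lengths in mm, mu in 1/mm
analytic_diffusion_2d <- function(x, z, mua, musp) {
  mut <- mua + musp
  D <- 1 / (2 * mut)
  mueff <- sqrt(mua / D)
  z0 <- 1 / mut
  zb <- (pi / 2) * D
  r1 <- sqrt(x^2 + (z - z0)^2)
  r2 <- sqrt(x^2 + (z + z0 + 2 * zb)^2)
  (besselK(mueff * r1, 0) - besselK(mueff * r2, 0)) / (2 * pi * D)
}
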