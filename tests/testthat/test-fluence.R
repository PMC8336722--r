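test_that("stacks contain one absorbed-energy map per wavelength and position", {
  ph <- sampleTrainingVolume(samplerConfig(extent = c(16, 10), pitch = 0.5,
                                           depthRange = c(2, 7),
                                           lateralRange = c(-5, 5)),
                             seed = 2)
  st <- simulateStack(ph)
  expect_identical(dim(st@H)[3:4], c(16L, 4L))
  expect_equal(prod(dim(st@H)[3:4]), 64)
  # H = phi * mu_a pointwise, nonnegative
  expect_true(all(st@H >= 0))
  f <- diffusionFluence(ph, illuminationGeometry(), 2, 5)
  expect_equal(energyMap(st, 5, 2), f * absorptionMap(ph, 5))
})

test_that("zero-absorption voxels have zero absorbed energy", {
  mua <- matrix(1, 20, 20); mua[10, 10] <- 0
  ph <- voxelPhantom(mua, matrix(15, 20, 20), pitch = 0.5, wavelengths = 800)
  st <- simulateStack(ph, illuminationGeometry(nPositions = 1))
  expect_identical(st@H[10, 10, 1, 1], 0)
  expect_gt(st@H[10, 11, 1, 1], 0)
})

test_that("a tube sees more energy from the nearest illumination", {
  bg <- chromophoreMixture(0.5, 0.01, "sulfate")
  tubes <- data.frame(x = -12, z = 5, radius = 0.4, saturation = 0.5,
                      orientation = "across", halfLength = NA)
  geom <- phantomGeometry(tubes, bg, extent = c(32, 14), pitch = 0.4)
  ph <- rasterizeOptics(geom)
  st <- simulateStack(ph)  # beams at -12, -4, 4, 12
  idx <- which(labelMap(ph) == 1L)
  for (w in seq_along(wavelengths(ph))) {
    near <- mean(energyMap(st, w, 1)[idx])
    far <- mean(energyMap(st, w, 4)[idx])
    expect_gt(near, far)
  }
})

test_that("the diffusion backend is deterministic and monotone in absorption", {
  ph <- homogeneous_phantom(0.5, 12, 30, 40, 0.5)
  il <- illuminationGeometry(nPositions = 1)
  f1 <- diffusionFluence(ph, il, 1, 1)
  f2 <- diffusionFluence(ph, il, 1, 1)
  expect_identical(f1, f2)
  ph2 <- homogeneous_phantom(1.0, 12, 30, 40, 0.5)
  f3 <- diffusionFluence(ph2, il, 1, 1)
  deep <- ((1:30) - 0.5) * 0.5 > 2
  expect_true(all(f3[deep, ] < f1[deep, ]))
})

test_that("diffusion matches the 2D semi-infinite closed form", {
  h <- 0.5; nz <- 60; nx <- 100
  ph <- homogeneous_phantom(0.1, 15, nz, nx, h)
  fd <- diffusionFluence(ph, illuminationGeometry(nPositions = 1,
                                                  beamFwhm = 0.5), 1, 1)
  zc <- ((1:nz) - 0.5) * h; ic <- 50
  xc <- ((1:nx) - 0.5) * h - nx * h / 2
  for (zz in c(5, 8, 11, 14)) {
    iz <- which.min(abs(zc - zz))
    ana <- analytic_diffusion_2d(xc[ic], zc[iz], 0.01, 1.5)
    expect_lt(abs(fd[iz, ic] / ana - 1), 0.10)
  }
})

test_that("Monte Carlo reproduces Beer-Lambert in a pure absorber", {
  h <- 0.2; nz <- 100; nx <- 41
  ph <- homogeneous_phantom(5, 0, nz, nx, h)  # mu_a = 0.5/mm, no scattering
  f <- mcFluence(ph, illuminationGeometry(nPositions = 1), 1, 1,
                 nPhotons = 1e4, seed = 3, pencil = TRUE)
  ic <- ceiling(nx / 2)
  z1 <- (0:(nz - 1)) * h
  ana <- (exp(-0.5 * z1) - exp(-0.5 * (z1 + h))) / 0.5 / h^2
  depths <- seq(5, 95, by = 10)
  expect_true(all(abs(f[depths, ic] / ana[depths] - 1) < 1e-9))
})

test_that("Monte Carlo conserves energy to the termination tolerance", {
  ph <- homogeneous_phantom(1, 10, 40, 40, 0.4)
  f <- mcFluence(ph, illuminationGeometry(nPositions = 1), 1, 1,
                 nPhotons = 2e4, seed = 5)
  bal <- attr(f, "deposited") + attr(f, "escaped") + attr(f, "dropped")
  expect_equal(bal, 1, tolerance = 1e-12)
  expect_lt(attr(f, "dropped"), 1e-6)
  expect_gte(attr(f, "deposited") + attr(f, "escaped"), 1 - 1e-6)
})

test_that("Monte Carlo is deterministic under a fixed seed", {
  ph <- homogeneous_phantom(1, 10, 30, 30, 0.4)
  il <- illuminationGeometry(nPositions = 2)
  a <- mcFluence(ph, il, 2, 1, nPhotons = 5000, seed = 11)
  b <- mcFluence(ph, il, 2, 1, nPhotons = 5000, seed = 11)
  expect_identical(as.vector(a), as.vector(b))
  c <- mcFluence(ph, il, 2, 1, nPhotons = 5000, seed = 12)
  expect_false(identical(as.vector(a), as.vector(c)))
})

test_that("an all-transparent medium transports ballistically", {
  ph <- homogeneous_phantom(0, 0, 20, 21, 0.5)
  f <- mcFluence(ph, illuminationGeometry(nPositions = 1), 1, 1,
                 nPhotons = 1000, seed = 2, pencil = TRUE)
  ic <- 11
  # every photon crosses every depth cell of the axis column
  expect_true(all(abs(f[, ic] - 0.5 / 0.25) < 1e-9))
  expect_equal(attr(f, "escaped"), 1)
})

test_that("spectral coloring distorts normalized tube spectra away from mu_a", {
  grid <- defaultWavelengthGrid()
  tubes <- data.frame(x = 0, z = 8, radius = 0.4, saturation = 0.6,
                      orientation = "across", halfLength = NA)
  dist_for_vf <- function(vf) {
    bg <- chromophoreMixture(0.5, vf, "sulfate")
    geom <- phantomGeometry(tubes, bg, extent = c(24, 12), pitch = 0.4)
    ph <- rasterizeOptics(geom, grid)
    st <- simulateStack(ph)
    s <- extractSamples(st, "lsd")
    mua_hat <- l1Normalize(
      mixtureAbsorption(chromophoreMixture(0.6, 1, "sulfate"), grid))
    mean(apply(featureMatrix(s), 1, function(r) sum(abs(r - mua_hat))))
  }
  d1 <- dist_for_vf(0.005); d2 <- dist_for_vf(0.02)
  expect_gt(d1, 0.01)   # coloring is nonzero
  expect_gt(d2, d1)     # and grows with background volume fraction
})

test_that("fluence maps are nonnegative and finite everywhere", {
  ph <- tiny_tube_phantom(seed = 9)
  st_d <- simulateStack(ph)
  expect_true(all(is.finite(st_d@H)) && all(st_d@H >= 0))
  f <- mcFluence(ph, illuminationGeometry(), 1, 1, nPhotons = 2000, seed = 1)
  expect_true(all(is.finite(f)) && all(f >= 0))
})
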