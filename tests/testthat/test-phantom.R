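test_that("sampled volumes respect the tube-count and parameter bounds", {
  cfg <- samplerConfig()
  for (seed in c(1, 17, 4242)) {
    ph <- sampleTrainingVolume(cfg, seed = seed, grid = c(700, 900))
    k <- length(tubeSaturations(ph))
    expect_gte(k, 6L); expect_lte(k, 18L)
    expect_true(all(tubeSaturations(ph) >= 0 & tubeSaturations(ph) <= 1))
    expect_gte(ph@background$volumeFraction, 0)
    expect_lte(ph@background$volumeFraction, 0.03)
  }
  one <- sampleTrainingVolume(
    samplerConfig(nSets = 1L, tubesPerSet = c(1L, 1L)),
    seed = 3, grid = c(700, 900))
  expect_length(tubeSaturations(one), 1L)
})

test_that("sampling is bit-for-bit reproducible under a fixed seed", {
  cfg <- samplerConfig()
  a <- sampleTrainingVolume(cfg, seed = 99, grid = c(700, 900))
  b <- sampleTrainingVolume(cfg, seed = 99, grid = c(700, 900))
  expect_identical(a@mua, b@mua)
  expect_identical(a@labels, b@labels)
  expect_identical(a@tubeSaturation, b@tubeSaturation)
})

test_that("sampler marginals match the training distribution", {
  cfg <- samplerConfig()
  sats <- c(); counts <- integer(0)
  for (seed in 1:500) {
    tubes <- milsd:::.with_seed(seed, milsd:::.sample_tubes(cfg))
    sats <- c(sats, tubes$saturation)
    counts <- c(counts, nrow(tubes))
  }
  expect_lt(abs(mean(sats) - 0.5), 0.05)
  expect_true(all(6:18 %in% counts))
  expect_true(all(counts >= 6 & counts <= 18))
})

test_that("impossible placements error after the retry budget", {
  # tubes too big for the volume
  cfg <- samplerConfig(nSets = 2L, tubesPerSet = c(9L, 9L), tubeRadius = 2,
                       extent = c(14, 14), depthRange = c(3, 10),
                       lateralRange = NULL, maxRetries = 20L)
  expect_error(sampleTrainingVolume(cfg, seed = 1, grid = 800),
               "retries|overlap|narrow")
})

test_that("deterministic layouts have the documented tube structure", {
  bg <- chromophoreMixture(0.5, 0.01, "sulfate")
  A <- buildLayout("A", c(0, 0.25, 0.5, 0.75, 1), bg, grid = c(700, 900))
  expect_length(tubeSaturations(A), 5L)
  expect_setequal(setdiff(unique(as.vector(labelMap(A))), 0L), 1:5)
  B <- buildLayout("B", c(0, 0.25, 0.5, 0.75, 1), bg, grid = c(700, 900))
  expect_length(tubeSaturations(B), 20L)
  # five arrays of four: two shallow (3.5 mm) and two deep (7.5 mm) each
  expect_equal(as.vector(table(B@geometry$tubes$z)), c(10L, 10L))
  C <- buildLayout("C", c(0.2, 0.8), bg, grid = c(700, 900))
  expect_length(tubeSaturations(C), 2L)
  expect_true(all(C@geometry$tubes$orientation == "along"))
  expect_error(buildLayout("A", c(0.5, 0.5), bg), "5 saturations")
  expect_error(buildLayout("C", c(0.5, 0.5, 0.5), bg), "2 saturations")
})

test_that("zero-volume-fraction background reduces to water-only absorption", {
  bg <- chromophoreMixture(0.5, 0, "sulfate")
  grid <- c(700, 900)
  ph <- buildLayout("A", rep(0.5, 5), bg, grid = grid)
  water <- bundledEndmembers("water", grid)[[1]]$mua
  i_bg <- which(labelMap(ph) == 0L)[1]
  expect_equal(ph@mua[, , 1][i_bg], water[1])
  expect_equal(ph@mua[, , 2][i_bg], water[2])
})

test_that("rasterization assigns the documented optical properties", {
  grid <- c(700, 900)
  bg <- chromophoreMixture(0.3, 0.02, "sulfate")
  tubes <- data.frame(x = 0, z = 5, radius = 0.4, saturation = 0.8,
                      orientation = "across", halfLength = NA)
  geom <- phantomGeometry(tubes, bg, extent = c(12, 10), pitch = 0.2)
  sc <- scatteringParams()
  ph <- rasterizeOptics(geom, grid, sc)
  em <- bundledEndmembers("sulfate", grid)
  tube_idx <- which(labelMap(ph) == 1L)
  expect_gt(length(tube_idx), 0)
  # tube mu_a is the pure mixture at volume fraction 1; tube mu_s' is 0
  expected <- mixtureAbsorption(chromophoreMixture(0.8, 1, "sulfate"),
                                grid, em)
  expect_true(all(abs(ph@mua[, , 1][tube_idx] - expected[1]) < 1e-12))
  expect_true(all(ph@musp[, , 1][tube_idx] == 0))
  # background mu_s' follows the scattering model
  bg_idx <- which(labelMap(ph) == 0L)[1]
  expect_equal(ph@musp[, , 1][bg_idx], reducedScattering(sc, 700))
  expect_equal(ph@musp[, , 2][bg_idx], reducedScattering(sc, 900))
})

test_that("rasterized tube area matches the disk area as pitch refines", {
  bg <- chromophoreMixture(0.5, 0.01, "sulfate")
  tubes <- data.frame(x = 0.013, z = 5.007, radius = 0.4, saturation = 0.5,
                      orientation = "across", halfLength = NA)
  counts <- vapply(c(0.1, 0.05), function(p) {
    geom <- phantomGeometry(tubes, bg, extent = c(10, 10), pitch = p)
    sum(labelMap(rasterizeOptics(geom, 800)) == 1L)
  }, numeric(1))
  area <- pi * 0.4^2
  expect_lt(abs(counts[1] * 0.1^2 / area - 1), 0.1)
  expect_lt(abs(counts[2] * 0.05^2 / area - 1), 0.1)
  # halving the pitch about quadruples the voxel count
  expect_lt(abs(counts[2] / counts[1] / 4 - 1), 0.1)
})

test_that("overlapping tubes are rejected at rasterization", {
  bg <- chromophoreMixture(0.5, 0.01, "sulfate")
  tubes <- data.frame(x = c(0, 0.2), z = c(5, 5), radius = 0.4,
                      saturation = c(0.2, 0.9),
                      orientation = "across", halfLength = NA)
  geom <- phantomGeometry(tubes, bg, extent = c(10, 10), pitch = 0.1)
  expect_error(rasterizeOptics(geom, 800), "overlap")
})
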