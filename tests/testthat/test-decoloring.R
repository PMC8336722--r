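test_that("L1 normalization scales to unit sum and rejects unusable input", {
  expect_equal(l1Normalize(c(1, 3)), c(0.25, 0.75))
  s <- runif(16)
  expect_equal(l1Normalize(7.3 * s), l1Normalize(s))
  expect_equal(sum(l1Normalize(s)), 1)
  expect_error(l1Normalize(rep(0, 16)), "unusable")
  expect_error(l1Normalize(c(-1, 2)), "nonnegative")
})

test_that("extraction yields one sample per tube voxel with the right widths", {
  ph <- tiny_tube_phantom(seed = 4)
  st <- simulateStack(ph)
  n_vox <- sum(labelMap(ph) > 0)
  mi <- extractSamples(st, "milsd", augmentMirror = TRUE)
  expect_equal(nrow(featureMatrix(mi)), 2 * n_vox)  # mirror doubles
  expect_equal(ncol(featureMatrix(mi)), 2 * 4)      # 2 wavelengths x 4 illum
  mi0 <- extractSamples(st, "milsd", augmentMirror = FALSE)
  expect_equal(nrow(featureMatrix(mi0)), n_vox)
  ls <- extractSamples(st, "lsd", augmentMirror = TRUE)  # mirror is a no-op
  expect_equal(nrow(featureMatrix(ls)), n_vox)
  expect_equal(ncol(featureMatrix(ls)), 2)
  # every wavelength block of every row is unit-L1
  f <- featureMatrix(mi)
  for (b in 1:4)
    expect_equal(rowSums(f[, (b - 1) * 2 + 1:2, drop = FALSE]),
                 rep(1, nrow(f)))
})

test_that("mirrored samples reverse the illumination block order", {
  ph <- tiny_tube_phantom(seed = 4)
  st <- simulateStack(ph)
  mi <- extractSamples(st, "milsd", augmentMirror = TRUE)
  f <- featureMatrix(mi)
  n <- nrow(f) / 2
  nw <- mi@nWavelengths
  straight <- f[1, ]
  mirrored <- f[n + 1, ]
  for (b in 1:4)
    expect_equal(mirrored[(b - 1) * nw + 1:nw],
                 straight[(4 - b) * nw + 1:nw])
  expect_equal(saturationLabels(mi)[1], saturationLabels(mi)[n + 1])
})

test_that("features are exactly invariant to per-voxel Gamma-A scaling", {
  ph <- tiny_tube_phantom(seed = 6)
  st <- simulateStack(ph)
  # apply a signal-formation scaling: Gamma(x) * A(x), wavelength-independent
  set.seed(31)
  gain <- matrix(runif(prod(dim(ph@mua)[1:2]), 0.2, 5),
                 dim(ph@mua)[1], dim(ph@mua)[2])
  st2 <- st
  for (w in seq_len(dim(st@H)[3]))
    for (i in seq_len(dim(st@H)[4]))
      st2@H[, , w, i] <- st@H[, , w, i] * gain
  for (mode in c("milsd", "lsd")) {
    a <- extractSamples(st, mode)
    b <- extractSamples(st2, mode)
    # exact up to the round-off of the normalizing division
    expect_equal(featureMatrix(a), featureMatrix(b), tolerance = 1e-14)
    expect_identical(saturationLabels(a), saturationLabels(b))
  }
})

test_that("linear unmixing exactly recovers uncolored mixtures", {
  grid <- defaultWavelengthGrid()
  em <- bundledEndmembers("sulfate", grid)
  set.seed(12)
  for (k in 1:25) {
    s <- runif(1); vf <- runif(1, 0.01, 1)
    spec <- l1Normalize(
      mixtureAbsorption(chromophoreMixture(s, vf, "sulfate"), grid, em))
    expect_lt(abs(linearUnmixing(spec, em) - s), 1e-6)
  }
  expect_equal(linearUnmixing(l1Normalize(em[[1]]$mua), em), 1.0)
  expect_equal(linearUnmixing(l1Normalize(em[[2]]$mua), em), 0.0)
})

test_that("linear unmixing flags undefined estimates instead of returning 0", {
  em <- bundledEndmembers("sulfate")
  expect_warning(out <- linearUnmixing(rep(0, 16), em), "undefined")
  expect_true(is.na(out))
  batch <- linearUnmixingBatch(rbind(rep(0, 16), l1Normalize(em[[1]]$mua)), em)
  expect_true(is.na(batch[1]) && abs(batch[2] - 1) < 1e-12)
})

test_that("spectral coloring induces linear-unmixing error on a deep tube", {
  grid <- defaultWavelengthGrid()
  em <- bundledEndmembers("sulfate", grid)
  bg <- chromophoreMixture(0.0, 0.01, "sulfate")
  tubes <- data.frame(x = 0, z = 7, radius = 0.4, saturation = 0.5,
                      orientation = "across", halfLength = NA)
  ph <- rasterizeOptics(phantomGeometry(tubes, bg, extent = c(24, 12),
                                        pitch = 0.4), grid)
  st <- simulateStack(ph)
  s <- extractSamples(st, "lsd")
  est <- linearUnmixingBatch(featureMatrix(s), em)
  expect_gt(median(abs(est - 0.5)), 0.01)
})

test_that("spectra sets combine and validate consistently", {
  ph <- tiny_tube_phantom(seed = 4)
  st <- simulateStack(ph)
  a <- extractSamples(st, "milsd", volumeId = 1L)
  b <- extractSamples(st, "milsd", volumeId = 2L)
  ab <- bindSpectraSets(list(a, b))
  expect_equal(nrow(featureMatrix(ab)),
               nrow(featureMatrix(a)) + nrow(featureMatrix(b)))
  expect_setequal(unique(sampleProvenance(ab)$volume), c(1L, 2L))
  ls <- extractSamples(st, "lsd")
  expect_error(bindSpectraSets(list(a, ls)), "different modes")
})
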