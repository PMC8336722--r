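test_that("wavelength grids are validated", {
  expect_identical(wavelengthGrid(), seq(680, 980, by = 20))
  expect_length(defaultWavelengthGrid(), 16L)
  expect_error(wavelengthGrid(c(700, 700)), "strictly increasing")
  expect_error(wavelengthGrid(c(-1, 700)), "positive")
})

test_that("mixture absorption is the linear two-endmember formula", {
  grid <- defaultWavelengthGrid()
  em <- bundledEndmembers("sulfate", grid)
  # independent per-wavelength scalar computation
  for (case in list(c(0.3, 0.02), c(0.9, 1), c(0, 0.5))) {
    mix <- chromophoreMixture(case[1], case[2], "sulfate")
    got <- mixtureAbsorption(mix, grid, em)
    expected <- vapply(seq_along(grid), function(w)
      case[2] * (case[1] * em[[1]]$mua[w] + (1 - case[1]) * em[[2]]$mua[w]),
      numeric(1))
    expect_equal(got, expected, tolerance = 1e-12)
  }
  # endpoint identity: saturation 1, volume fraction 1 is the Cu endmember
  expect_equal(
    mixtureAbsorption(chromophoreMixture(1, 1, "sulfate"), grid, em),
    em[[1]]$mua)
  # zero volume fraction is the zero spectrum
  expect_equal(
    mixtureAbsorption(chromophoreMixture(0.7, 0, "sulfate"), grid, em),
    rep(0, 16))
  # the rCu_bg = 50%, SVF = 1% background construction
  bg <- mixtureAbsorption(chromophoreMixture(0.5, 0.01, "sulfate"), grid, em)
  expect_equal(bg, 0.005 * em[[1]]$mua + 0.005 * em[[2]]$mua)
})

test_that("mixture parameters are validated", {
  expect_error(chromophoreMixture(1.2, 0.5), "saturation")
  expect_error(chromophoreMixture(0.5, -0.1), "volumeFraction")
})

test_that("reduced scattering follows the power-law model", {
  p <- scatteringParams(42.4, 0.62, 1.0)
  expect_equal(reducedScattering(p, 500), 42.4)
  # both power terms are 1 at 500 nm whatever the parameters
  for (k in 1:5) {
    pr <- scatteringParams(runif(1, 1, 100), runif(1), runif(1, 0.2, 3))
    expect_equal(reducedScattering(pr, 500), pr$mus500)
  }
  expect_equal(reducedScattering(p, 750), 15.93402, tolerance = 1e-6)
  expect_equal(reducedScattering(scatteringParams(16, 1, 1), 1000), 1.0)
  expect_error(reducedScattering(p, c(700, -5)), "positive")
})

test_that("scattering model fit recovers parameters", {
  truth <- scatteringParams(35, 0.5, 1.3)
  wl <- seq(600, 840, by = 20)
  y <- reducedScattering(truth, wl)
  fit <- fitScatteringModel(wl, y, init = scatteringParams())
  expect_equal(fit$mus500, truth$mus500, tolerance = 1e-6)
  expect_equal(fit$fray, truth$fray, tolerance = 1e-6)
  expect_equal(fit$bmie, truth$bmie, tolerance = 1e-6)
  # residual norm does not exceed the residual at the initial guess
  rss <- function(p) sum((y - reducedScattering(p, wl))^2)
  expect_lte(rss(fit), rss(scatteringParams()))
})

test_that("scattering fit tolerates multiplicative noise", {
  truth <- scatteringParams(42.4, 0.62, 1.0)
  wl <- seq(600, 840, by = 20)
  set.seed(421)
  y <- reducedScattering(truth, wl) * (1 + 0.02 * rnorm(length(wl)))
  fit <- fitScatteringModel(wl, y)
  expect_lt(abs(fit$mus500 / truth$mus500 - 1), 0.05)
})

test_that("degenerate scattering fits are rejected", {
  expect_error(fitScatteringModel(c(700, 700, 700), c(15, 15, 15)),
               "degenerate")
  expect_error(fitScatteringModel(c(700, 800), c(15, 12)), "at least 3")
})

test_that("bundled endmembers are structurally sound", {
  hb <- bundledEndmembers("hemoglobin")
  expect_length(hb, 2L)
  expect_identical(vapply(hb, function(e) e$name, character(1)),
                   c("HbO2", "Hb"))
  for (fam in c("sulfate", "hemoglobin", "water"))
    for (e in bundledEndmembers(fam)) {
      expect_length(e$mua, 16L)
      expect_true(all(is.finite(e$mua)) && all(e$mua >= 0))
    }
  expect_error(bundledEndmembers("melanin"))
})

test_that("sulfate endmembers cross like the hemoglobin isosbestic point", {
  su <- bundledEndmembers("sulfate")
  sgn <- sign(su[[1]]$mua - su[[2]]$mua)
  expect_gte(sum(diff(sgn) != 0), 1L)
  # Ni (Hb-like) dominates at 680, decays; Cu (HbO2-like) peaks near 810
  expect_gt(su[[2]]$mua[1], su[[1]]$mua[1])
  wl <- su[[1]]$wavelengths
  expect_true(wl[which.max(su[[1]]$mua)] %in% c(780, 800, 820))
})

test_that("off-range wavelength requests name the tabulated range", {
  expect_error(bundledEndmembers("hemoglobin", grid = c(500, 700)),
               "660-1000")
})

test_that("endmember tables round-trip through the plain-text loader", {
  e <- endmemberSpectrum("x", c(700, 800, 900), c(1, 2, 3))
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# test", paste(e$wavelengths, e$mua, sep = "\t")), f)
  r <- readEndmemberTable(f, "x")
  expect_equal(r$mua, e$mua)
  writeLines(c("800\t1", "700\t2"), f)
  expect_error(readEndmemberTable(f), "increasing")
})
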