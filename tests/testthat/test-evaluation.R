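test_that("ROI segmentation returns exactly the ceiling-count brightest pixels", {
  set.seed(41)
  img <- matrix(runif(60 * 80), 60, 80)
  for (frac in c(0.15, 0.5, 0.07, 1)) {
    roi <- roiSpec(x = -5, z = 3, width = 3.75, height = 3.3,
                   fraction = frac)
    idx <- roiSegment(img, roi, pitch = 0.25)
    cols <- which(((1:80) - 0.5) * 0.25 - 10 >= -5 &
                  ((1:80) - 0.5) * 0.25 - 10 <= -5 + 3.75)
    rows <- which(((1:60) - 0.5) * 0.25 >= 3 &
                  ((1:60) - 0.5) * 0.25 <= 3 + 3.3)
    n_roi <- length(cols) * length(rows)
    expect_length(idx, ceiling(frac * n_roi))
    # selected values are exactly the k largest in the ROI
    all_idx <- as.vector(outer(rows, (cols - 1L) * 60L, `+`))
    expect_equal(sort(img[idx], decreasing = TRUE),
                 sort(img[all_idx], decreasing = TRUE)[seq_along(idx)])
  }
})

test_that("constant images tie-break in row-major order", {
  img <- matrix(1, 40, 40)
  roi <- roiSpec(x = -2, z = 1, width = 2, height = 2, fraction = 0.15)
  idx <- roiSegment(img, roi, pitch = 0.5)
  cols <- which(((1:40) - 0.5) * 0.5 - 10 >= -2 &
                ((1:40) - 0.5) * 0.5 - 10 <= 0)
  rows <- which(((1:40) - 0.5) * 0.5 >= 1 & ((1:40) - 0.5) * 0.5 <= 3)
  all_idx <- as.vector(outer(rows, (cols - 1L) * 40L, `+`))
  k <- ceiling(0.15 * length(all_idx))
  expect_identical(idx, all_idx[seq_len(k)])
})

test_that("a bright disk is segmented entirely inside the disk", {
  nz <- 60; nx <- 60; pitch <- 0.25
  zc <- ((1:nz) - 0.5) * pitch
  xc <- ((1:nx) - 0.5) * pitch - nx * pitch / 2
  img <- matrix(0.1, nz, nx)
  disk <- outer(zc - 5, xc - 0, function(a, b) a^2 + b^2) <= 0.81
  img[disk] <- 1 + img[disk]
  roi <- roiSpec(x = -1.85, z = 3.35, width = 3.75, height = 3.3,
                 fraction = 0.15)
  idx <- roiSegment(img, roi, pitch = pitch)
  expect_true(all(disk[idx]))
})

test_that("empty ROIs error", {
  expect_error(roiSegment(matrix(1, 10, 10), roiSpec(50, 50, 2, 2, 0.15),
                          pitch = 0.5), "empty ROI")
})

test_that("error summaries match hand-computed statistics", {
  s <- summarizeErrors(c(-0.01, 0.02, 0.03) + 0.5, rep(0.5, 3))
  expect_equal(signedStats(s)[["q2"]], 2)
  expect_equal(signedStats(s)[["mean"]], 4 / 3)
  one <- summarizeErrors(0.55, 0.5)
  expect_equal(unname(signedStats(one)[c("q1", "q2", "q3", "p90")]),
               rep(5, 4))
  expect_equal(signedStats(one)[["iqr"]], 0)
  expect_error(summarizeErrors(numeric(0), numeric(0)), "no samples")
  expect_error(summarizeErrors(c(0.1, 0.2), 0.1), "same length")
})

test_that("quantiles agree with the brute-force sorted-percentile oracle", {
  set.seed(99)
  for (k in 1:50) {
    n <- sample(2:60, 1)
    est <- runif(n); tru <- runif(n)
    s <- summarizeErrors(est, tru)
    d <- (est - tru) * 100
    expect_equal(signedStats(s)[["q1"]], brute_force_quantile(d, 0.25))
    expect_equal(signedStats(s)[["q2"]], brute_force_quantile(d, 0.5))
    expect_equal(signedStats(s)[["q3"]], brute_force_quantile(d, 0.75))
    expect_equal(absoluteStats(s)[["p90"]],
                 brute_force_quantile(abs(d), 0.9))
  }
})

test_that("quantile identities hold on random inputs", {
  set.seed(7)
  for (k in 1:30) {
    n <- sample(1:40, 1)
    s <- summarizeErrors(runif(n), rep(0.5, n))
    for (b in list(signedStats(s), absoluteStats(s))) {
      expect_lte(b[["q1"]], b[["q2"]])
      expect_lte(b[["q2"]], b[["q3"]])
      expect_equal(b[["iqr"]], b[["q3"]] - b[["q1"]])
    }
    expect_gte(absoluteStats(s)[["p90"]], absoluteStats(s)[["q3"]])
  }
})

test_that("report tables have the reference layout and round-trip", {
  set.seed(5)
  sums <- list(
    "rf.milsd.B" = summarizeErrors(runif(40), runif(40)),
    "lu..B" = summarizeErrors(runif(40), runif(40)))
  tab <- reportTable(sums)
  expect_equal(nrow(tab), 2L)
  expect_equal(sum(vapply(tab, is.numeric, logical(1))), 9L)
  expect_identical(tab$model, c("rf", "lu"))
  expect_identical(tab$mode, c("milsd", ""))
  txt <- formatReportTable(tab)
  back <- parseReportTable(txt)
  for (cn in names(tab)[4:12])
    expect_equal(back[[cn]], tab[[cn]], tolerance = 1e-12)
  empty <- reportTable(list())
  expect_equal(nrow(empty), 0L)
  expect_match(formatReportTable(empty), "^model\\t")
})
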