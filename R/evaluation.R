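## ROI segmentation rules, estimation-error statistics and tabular
## reporting.  Errors are reported in percentage points (pp):
## delta = (estimate - truth) * 100.

#' Rectangular ROI with a threshold fraction
#'
#' @param x,z Upper-left corner of the rectangle in mm (x lateral from the
#'   volume center, z depth).
#' @param width,height Rectangle size in mm.
#' @param fraction Fraction of the brightest pixels to segment as tube,
#'   in (0, 1].  The reference protocol uses 0.15 for compact transversal
#'   ROIs and 0.50 for elongated longitudinal ROIs.
#' @return Object of class \code{"RoiSpec"}.
#' @export
roiSpec <- function(x, z, width = 3.75, height = 3.3, fraction = 0.15) {
  stopifnot(width > 0, height > 0, fraction > 0, fraction <= 1)
  structure(list(x = as.numeric(x), z = as.numeric(z),
                 width = as.numeric(width), height = as.numeric(height),
                 fraction = as.numeric(fraction)),
            class = "RoiSpec")
}

#' Threshold segmentation of the brightest ROI pixels
#'
#' Selects exactly \code{ceiling(fraction * N)} pixels with the highest
#' mean signal inside the ROI, where N is the ROI pixel count.  Ties are
#' broken deterministically in row-major (within-column, then column)
#' order of the image matrix.
#'
#' @param meanSignal Matrix `[nz, nx]` of the mean (over wavelengths and
#'   illuminations) signal.
#' @param roi A \code{RoiSpec}.
#' @param pitch Pixel pitch in mm.
#' @param extent c(lateral, depth) image extent in mm (lateral centered on
#'   0); defaults to the full matrix.
#' @return Integer vector of linear pixel indices into \code{meanSignal}.
#' @export
roiSegment <- function(meanSignal, roi, pitch,
                       extent = c(ncol(meanSignal), nrow(meanSignal)) * pitch) {
  stopifnot(inherits(roi, "RoiSpec"), is.matrix(meanSignal))
  nz <- nrow(meanSignal); nx <- ncol(meanSignal)
  xc <- (seq_len(nx) - 0.5) * pitch - extent[1] / 2
  zc <- (seq_len(nz) - 0.5) * pitch
  cols <- which(xc >= roi$x & xc <= roi$x + roi$width)
  rows <- which(zc >= roi$z & zc <= roi$z + roi$height)
  if (!length(cols) || !length(rows)) stop("empty ROI")
  idx <- as.vector(outer(rows, (cols - 1L) * nz, `+`))  # row-major in-ROI
  k <- as.integer(ceiling(roi$fraction * length(idx)))
  vals <- meanSignal[idx]
  ord <- order(-vals, seq_along(idx))  # stable: first occurrence wins ties
  idx[ord[seq_len(k)]]
}

#' ErrorStats: descriptive statistics of estimation errors
#'
#' Signed and absolute error summaries in percentage points: mean, first
#' quartile Q1, median Q2, third quartile Q3, IQR = Q3 - Q1, and the 90th
#' percentile P90.  Quantiles use linear interpolation between order
#' statistics.
#'
#' @slot signed Named numeric: mean, q1, q2, q3, iqr, p90 of signed errors.
#' @slot absolute Same statistics of absolute errors.
#' @slot n Sample count.
#' @export
setClass("ErrorStats",
  representation(signed = "numeric", absolute = "numeric", n = "integer"))

setValidity("ErrorStats", function(object) {
  need <- c("mean", "q1", "q2", "q3", "iqr", "p90")
  if (!all(need %in% names(object@signed)) ||
      !all(need %in% names(object@absolute)))
    return("signed/absolute must contain mean, q1, q2, q3, iqr, p90")
  for (s in list(object@signed, object@absolute)) {
    if (s[["q1"]] > s[["q2"]] + 1e-12 || s[["q2"]] > s[["q3"]] + 1e-12)
      return("quantiles must be ordered Q1 <= Q2 <= Q3")
    if (abs(s[["iqr"]] - (s[["q3"]] - s[["q1"]])) > 1e-9)
      return("IQR must equal Q3 - Q1")
  }
  if (object@absolute[["p90"]] < object@absolute[["q3"]] - 1e-12)
    return("absolute P90 must be >= absolute Q3")
  TRUE
})

#' @describeIn ErrorStats-class Compact description.
#' @param object An \code{ErrorStats}.
#' @export
setMethod("show", "ErrorStats", function(object) {
  cat(sprintf("ErrorStats (n = %d): signed Q2 %.2f pp, |error| Q2 %.2f pp, IQR %.2f, P90 %.2f\n",
              object@n, object@signed[["q2"]], object@absolute[["q2"]],
              object@absolute[["iqr"]], object@absolute[["p90"]]))
})

#' @name ErrorStats-accessors
#' @title Accessors for ErrorStats
#' @param x An \code{ErrorStats}.
#' @return Named numeric vector of statistics, or the count.
NULL

#' @rdname ErrorStats-accessors
#' @export
signedStats <- function(x) x@signed
#' @rdname ErrorStats-accessors
#' @export
absoluteStats <- function(x) x@absolute
#' @rdname ErrorStats-accessors
#' @export
sampleCount <- function(x) x@n

.stat_block <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  c(mean = mean(v), q1 = q[1], q2 = q[2], q3 = q[3],
    iqr = q[3] - q[1], p90 = q[4])
}

#' Summarize estimation errors
#'
#' Computes the error distribution statistics of saturation estimates
#' against ground truth, in percentage points.
#'
#' @param estimates Estimated saturations in `[0, 1]` (NAs are removed
#'   pairwise with their truths).
#' @param truths Ground-truth saturations in `[0, 1]`, same length.
#' @return An \code{ErrorStats}.
#' @export
#' @examples
#' summarizeErrors(c(0.49, 0.52, 0.53), c(0.5, 0.5, 0.5))
summarizeErrors <- function(estimates, truths) {
  if (length(estimates) != length(truths))
    stop("estimates and truths must have the same length")
  ok <- !is.na(estimates) & !is.na(truths)
  estimates <- estimates[ok]; truths <- truths[ok]
  if (!length(estimates)) stop("no samples to summarize")
  delta <- (estimates - truths) * 100
  new("ErrorStats", signed = .stat_block(delta),
      absolute = .stat_block(abs(delta)), n = length(delta))
}

#' Error-summary report table
#'
#' Emits the standard report layout: one row per (model, mode, test set)
#' with the signed-error block (mean, Q1, Q2, Q3) and the absolute-error
#' block (mean, Q1, Q2, Q3, P90), all in percentage points.
#'
#' @param summaries Named list of \code{ErrorStats}; names of the form
#'   \code{"model.mode.set"} (missing parts may be empty), or a list with
#'   explicit \code{model}, \code{mode}, \code{set} attributes supplied via
#'   \code{keys}.
#' @param keys Optional data.frame with columns model, mode, set (one row
#'   per summary), overriding the parsed names.
#' @return data.frame with identifier columns and 9 numeric columns.
#' @export
reportTable <- function(summaries, keys = NULL) {
  if (!length(summaries)) {
    return(data.frame(model = character(0), mode = character(0),
                      set = character(0), mean = numeric(0), q1 = numeric(0),
                      q2 = numeric(0), q3 = numeric(0), abs_mean = numeric(0),
                      abs_q1 = numeric(0), abs_q2 = numeric(0),
                      abs_q3 = numeric(0), abs_p90 = numeric(0)))
  }
  if (is.null(keys)) {
    parts <- strsplit(names(summaries), ".", fixed = TRUE)
    keys <- data.frame(
      model = vapply(parts, function(p) p[1] %||% "", character(1)),
      mode = vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                    character(1)),
      set = vapply(parts, function(p) if (length(p) > 2) p[3] else "",
                   character(1)))
  }
  rows <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    stopifnot(is(s, "ErrorStats"))
    data.frame(model = keys$model[i], mode = keys$mode[i], set = keys$set[i],
               mean = s@signed[["mean"]], q1 = s@signed[["q1"]],
               q2 = s@signed[["q2"]], q3 = s@signed[["q3"]],
               abs_mean = s@absolute[["mean"]], abs_q1 = s@absolute[["q1"]],
               abs_q2 = s@absolute[["q2"]], abs_q3 = s@absolute[["q3"]],
               abs_p90 = s@absolute[["p90"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize / parse a report table
#'
#' Tab-separated text round trip: \code{parseReportTable(formatReportTable(x))}
#' reproduces \code{x}.
#'
#' @param table data.frame as returned by \code{\link{reportTable}}.
#' @return \code{formatReportTable}: a single TSV string (header always
#'   present).
#' @export
formatReportTable <- function(table) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(format(table, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @rdname formatReportTable
#' @param text TSV text produced by \code{formatReportTable}.
#' @export
parseReportTable <- function(text) {
  df <- utils::read.table(text = text, sep = "\t", header = TRUE,
                          colClasses = c(rep("character", 3),
                                         rep("numeric", 9)))
  df
}
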