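## Feature construction for learned spectral decoloring and the linear
## spectral unmixing baseline.
##
## The optoacoustic signal at a pixel factorizes as
##   S(x, lambda) = Gamma(x) * A(x) * H(x, lambda),
## with Gamma the (wavelength-independent) Grueneisen parameter and A the
## wavelength-independent acoustic reconstruction factor.  Normalizing each
## spectrum by its L1 norm removes Gamma * A exactly, so normalized signal
## spectra coincide with normalized absorbed-energy spectra and estimators
## trained on simulated H transfer to measured S.

#' L1-normalize a spectrum
#'
#' @param x Nonnegative numeric vector with at least one strictly positive
#'   entry.
#' @return \code{x / sum(x)}; sums to 1 and is proportional to the input,
#'   hence invariant to any positive scaling of \code{x}.
#' @export
#' @examples
#' l1Normalize(c(1, 3))
l1Normalize <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("spectrum must be nonnegative")
  s <- sum(x)
  if (!is.finite(s) || s <= 0)
    stop("unusable sample: spectrum has no positive content")
  x / s
}

#' SpectraSet: labeled decoloring features
#'
#' Per-sample feature matrix for the decoloring estimators.  In LSD mode a
#' sample is the single mean-illumination spectrum, L1-normalized (width =
#' number of wavelengths).  In MI-LSD mode each per-illumination spectrum is
#' L1-normalized separately and the blocks are concatenated in illumination
#' order (width = wavelengths x illuminations).
#'
#' @slot features Numeric matrix, one row per sample; every wavelength
#'   block of every row sums to 1.
#' @slot labels Ground-truth saturation per sample, in `[0, 1]`.
#' @slot mode \code{"lsd"} or \code{"milsd"}.
#' @slot nWavelengths Wavelengths per block.
#' @slot nIllum Illumination positions per sample (1 for lsd).
#' @slot provenance data.frame: volume, tube, voxel, mirrored.
#' @slot dropped Number of voxels dropped for unusable (all-zero) spectra.
#' @export
setClass("SpectraSet",
  representation(features = "matrix", labels = "numeric", mode = "character",
                 nWavelengths = "integer", nIllum = "integer",
                 provenance = "data.frame", dropped = "integer"))

setValidity("SpectraSet", function(object) {
  if (nrow(object@features) != length(object@labels))
    return("one label per feature row required")
  if (!object@mode %in% c("lsd", "milsd")) return("mode must be lsd or milsd")
  nb <- if (object@mode == "lsd") 1L else object@nIllum
  if (ncol(object@features) != nb * object@nWavelengths && nrow(object@features))
    return("feature width must be nWavelengths x blocks")
  if (length(object@labels) &&
      (any(object@labels < 0) || any(object@labels > 1)))
    return("labels must be in [0, 1]")
  if (nrow(object@features)) {
    bs <- vapply(seq_len(nb), function(b) {
      cols <- (b - 1L) * object@nWavelengths + seq_len(object@nWavelengths)
      max(abs(rowSums(object@features[, cols, drop = FALSE]) - 1))
    }, numeric(1))
    if (max(bs) > 1e-8) return("every wavelength block must be L1-normalized")
  }
  TRUE
})

#' @describeIn SpectraSet-class Compact description.
#' @param object A \code{SpectraSet}.
#' @export
setMethod("show", "SpectraSet", function(object) {
  cat(sprintf("SpectraSet (%s): %d samples x %d features (%d wavelengths x %d blocks), %d dropped\n",
              object@mode, nrow(object@features), ncol(object@features),
              object@nWavelengths, if (object@mode == "lsd") 1L else object@nIllum,
              object@dropped))
})

#' @name SpectraSet-accessors
#' @title Accessors for SpectraSet
#' @param x A \code{SpectraSet}.
#' @return The requested component.
NULL

#' @rdname SpectraSet-accessors
#' @export
featureMatrix <- function(x) x@features
#' @rdname SpectraSet-accessors
#' @export
saturationLabels <- function(x) x@labels
#' @rdname SpectraSet-accessors
#' @export
sampleProvenance <- function(x) x@provenance
#' @rdname SpectraSet-accessors
#' @export
droppedSamples <- function(x) x@dropped

# construct a SpectraSet from raw pieces (features already normalized)
.spectra_set <- function(features, labels, mode, nw, ni, provenance, dropped) {
  new("SpectraSet", features = features, labels = as.numeric(labels),
      mode = mode, nWavelengths = as.integer(nw), nIllum = as.integer(ni),
      provenance = provenance, dropped = as.integer(dropped))
}

#' Extract labeled decoloring samples from an absorbed-energy stack
#'
#' Takes one sample per tube voxel of the stack's phantom.  In
#' \code{"milsd"} mode the per-illumination spectra are each L1-normalized
#' and concatenated in illumination order; mirror augmentation additionally
#' appends each sample with the illumination order reversed (a data
#' augmentation exploiting the left-right symmetry of the illumination
#' line array), doubling the sample count.  In \code{"lsd"} mode the mean
#' over illuminations is taken first and then L1-normalized (the
#' fair-comparison single-spectrum input: same delivered energy as MI-LSD),
#' and mirroring is a no-op.  Voxels whose spectrum is all-zero in any
#' illumination are dropped and counted.
#'
#' @param stack An \code{EnergyStack}.
#' @param mode \code{"milsd"} or \code{"lsd"}.
#' @param augmentMirror Append mirrored-illumination copies (milsd only).
#' @param volumeId Integer recorded in the provenance.
#' @return A \code{SpectraSet}.
#' @export
extractSamples <- function(stack, mode = c("milsd", "lsd"),
                           augmentMirror = FALSE, volumeId = NA_integer_) {
  stopifnot(is(stack, "EnergyStack"))
  mode <- match.arg(mode)
  ph <- stack@phantom
  idx <- which(ph@labels != 0L)
  d <- dim(stack@H)
  nw <- d[3]; ni <- d[4]
  if (!length(idx)) {
    return(.spectra_set(matrix(0, 0, if (mode == "lsd") nw else nw * ni),
                        numeric(0), mode, nw, ni,
                        data.frame(volume = integer(0), tube = integer(0),
                                   voxel = integer(0), mirrored = logical(0)),
                        0L))
  }
  npix <- d[1] * d[2]
  Hm <- matrix(stack@H, npix, nw * ni)  # [pixel, (w, i)]
  spec <- Hm[idx, , drop = FALSE]       # [sample, w*i]
  labs <- ph@tubeSaturation[ph@labels[idx]]
  tube <- ph@labels[idx]

  if (mode == "lsd") {
    m <- matrix(0, length(idx), nw)
    for (i in seq_len(ni))
      m <- m + spec[, (i - 1L) * nw + seq_len(nw), drop = FALSE]
    m <- m / ni
    keep <- rowSums(m) > 0
    m <- m[keep, , drop = FALSE] / rowSums(m[keep, , drop = FALSE])
    prov <- data.frame(volume = volumeId, tube = tube[keep],
                       voxel = idx[keep], mirrored = FALSE)
    return(.spectra_set(m, labs[keep], "lsd", nw, ni, prov,
                        sum(!keep)))
  }

  # milsd: normalize each illumination block separately
  keep <- rep(TRUE, length(idx))
  blocks <- vector("list", ni)
  for (i in seq_len(ni)) {
    b <- spec[, (i - 1L) * nw + seq_len(nw), drop = FALSE]
    rs <- rowSums(b)
    keep <- keep & rs > 0
    blocks[[i]] <- b
  }
  feats <- do.call(cbind, lapply(blocks, function(b) {
    b <- b[keep, , drop = FALSE]
    b / rowSums(b)
  }))
  labs2 <- labs[keep]; tube2 <- tube[keep]; vox2 <- idx[keep]
  prov <- data.frame(volume = volumeId, tube = tube2, voxel = vox2,
                     mirrored = FALSE)
  if (augmentMirror && nrow(feats)) {
    rev_cols <- as.vector(vapply(rev(seq_len(ni)), function(i)
      (i - 1L) * nw + seq_len(nw), integer(nw)))
    feats <- rbind(feats, feats[, rev_cols, drop = FALSE])
    labs2 <- c(labs2, labs2)
    prov <- rbind(prov, transform(prov, mirrored = TRUE))
  }
  .spectra_set(feats, labs2, "milsd", nw, ni, prov, sum(!keep))
}

#' Combine SpectraSets
#'
#' Row-binds compatible \code{SpectraSet}s (same mode and widths).
#'
#' @param ... \code{SpectraSet} objects.
#' @return A combined \code{SpectraSet}.
#' @export
bindSpectraSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "SpectraSet"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1, all(vapply(sets, is, logical(1), "SpectraSet")))
  m <- unique(vapply(sets, function(s) s@mode, character(1)))
  if (length(m) != 1L) stop("cannot combine sets of different modes")
  .spectra_set(do.call(rbind, lapply(sets, featureMatrix)),
               unlist(lapply(sets, saturationLabels)),
               m, sets[[1]]@nWavelengths, sets[[1]]@nIllum,
               do.call(rbind, lapply(sets, sampleProvenance)),
               sum(vapply(sets, droppedSamples, integer(1))))
}

#' Linear spectral unmixing of a normalized spectrum
#'
#' Nonnegative least-squares fit of a spectrum to a linear combination of
#' the two endmember absorption spectra,
#' \eqn{S \approx c_1 E_1 + c_0 E_0} with \eqn{c_1, c_0 \ge 0}, returning
#' the saturation estimate \eqn{c_1 / (c_1 + c_0)} clipped to `[0, 1]`.
#' For two endmembers the NNLS solution is computed exactly in closed form
#' (unconstrained 2x2 solve plus active-set fallback).
#'
#' @param spectrum Numeric spectrum (typically unit-L1).
#' @param endmembers List of two \code{EndmemberSpectrum}s on the same grid
#'   (oxygenated-like first), or a 2-column matrix of endmember spectra.
#' @return Saturation estimate in `[0, 1]`, or \code{NA} (with a warning)
#'   when both fitted coefficients are zero.
#' @export
linearUnmixing <- function(spectrum, endmembers) {
  E <- .endmember_matrix(endmembers, length(spectrum))
  out <- .lu_batch(matrix(as.numeric(spectrum), nrow = 1), E)
  if (is.na(out)) warning("linear unmixing undefined: both coefficients zero")
  out
}

#' Batch linear unmixing
#'
#' @param spectra Matrix, one spectrum per row.
#' @param endmembers As in \code{\link{linearUnmixing}}.
#' @return Numeric vector of saturation estimates (NA where undefined).
#' @export
linearUnmixingBatch <- function(spectra, endmembers) {
  E <- .endmember_matrix(endmembers, ncol(spectra))
  .lu_batch(spectra, E)
}

.endmember_matrix <- function(endmembers, nw) {
  E <- if (is.matrix(endmembers)) endmembers
       else cbind(endmembers[[1]]$mua, endmembers[[2]]$mua)
  if (nrow(E) != nw)
    stop("endmember spectra and input spectra have different lengths")
  E
}

# exact 2-endmember NNLS over rows of S
.lu_batch <- function(S, E) {
  e1 <- E[, 1]; e0 <- E[, 2]
  a11 <- sum(e1 * e1); a00 <- sum(e0 * e0); a10 <- sum(e1 * e0)
  b1 <- as.vector(S %*% e1); b0 <- as.vector(S %*% e0)
  det <- a11 * a00 - a10 * a10
  c1 <- (b1 * a00 - b0 * a10) / det
  c0 <- (b0 * a11 - b1 * a10) / det
  neg <- c1 < 0 | c0 < 0
  if (any(neg)) {
    # active-set fallback: clamp each coefficient, keep the better fit
    c1a <- pmax(0, b1 / a11)                 # c0 = 0
    c0b <- pmax(0, b0 / a00)                 # c1 = 0
    ss <- rowSums(S * S)
    ra <- ss - 2 * c1a * b1 + c1a^2 * a11
    rb <- ss - 2 * c0b * b0 + c0b^2 * a00
    use_a <- ra <= rb
    c1[neg] <- ifelse(use_a[neg], c1a[neg], 0)
    c0[neg] <- ifelse(use_a[neg], 0, c0b[neg])
  }
  tot <- c1 + c0
  out <- ifelse(tot > 0, pmin(1, pmax(0, c1 / tot)), NA_real_)
  out
}
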