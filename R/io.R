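## Self-describing directory container for phantoms and spectra sets:
## plain-text TSV arrays plus a JSON sidecar holding shapes, units and
## provenance.  The absorbed-energy array is stored with the documented
## dimension order [illumination, wavelength, z, x] flattened over rows of
## (illumination, wavelength) blocks.

#' Write / read a VoxelPhantom container
#'
#' Writes a directory with \code{mu_a.tsv}, \code{mu_s_prime.tsv} (one row
#' per wavelength, voxels flattened column-major), \code{labels.tsv} and
#' \code{meta.json}.
#'
#' @param phantom A \code{VoxelPhantom}.
#' @param dir Target directory (created).
#' @return \code{writePhantom}: \code{dir}, invisibly;
#'   \code{readPhantom}: the reconstructed \code{VoxelPhantom}.
#' @export
writePhantom <- function(phantom, dir) {
  stopifnot(is(phantom, "VoxelPhantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(phantom@mua)
  flat <- function(a) t(matrix(a, d[1] * d[2], d[3]))
  utils::write.table(flat(phantom@mua), file.path(dir, "mu_a.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(flat(phantom@musp), file.path(dir, "mu_s_prime.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(phantom@labels, file.path(dir, "labels.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(shape = d, pitch = phantom@pitch, extent = phantom@extent,
         wavelengths = phantom@wavelengths, units = "1/cm; mm",
         tubeSaturation = phantom@tubeSaturation,
         family = phantom@family, background = phantom@background),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$shape)
  unflat <- function(f)
    array(t(as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))), d)
  labels <- as.matrix(utils::read.table(file.path(dir, "labels.tsv"),
                                        sep = "\t"))
  dimnames(labels) <- NULL
  voxelPhantom(unflat("mu_a.tsv"), unflat("mu_s_prime.tsv"),
               pitch = meta$pitch, wavelengths = meta$wavelengths,
               labels = labels, tubeSaturation = meta$tubeSaturation,
               family = meta$family,
               background = as.list(meta$background))
}

#' Write / read a SpectraSet container
#'
#' Writes \code{features.tsv}, \code{labels.tsv}, \code{provenance.tsv} and
#' \code{meta.json} into a directory.
#'
#' @param set A \code{SpectraSet}.
#' @param dir Target directory (created).
#' @return \code{writeSpectraSet}: \code{dir}, invisibly;
#'   \code{readSpectraSet}: the reconstructed \code{SpectraSet}.
#' @export
writeSpectraSet <- function(set, dir) {
  stopifnot(is(set, "SpectraSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(featureMatrix(set), file.path(dir, "features.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(label = saturationLabels(set)),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE)
  utils::write.table(sampleProvenance(set), file.path(dir, "provenance.tsv"),
                     sep = "\t", row.names = FALSE)
  jsonlite::write_json(
    list(mode = set@mode, nWavelengths = set@nWavelengths,
         nIllum = set@nIllum, dropped = set@dropped,
         nSamples = nrow(featureMatrix(set))),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeSpectraSet
#' @export
readSpectraSet <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  feats <- as.matrix(utils::read.table(file.path(dir, "features.tsv"),
                                       sep = "\t"))
  dimnames(feats) <- NULL
  labs <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                            header = TRUE)$label
  prov <- utils::read.table(file.path(dir, "provenance.tsv"), sep = "\t",
                            header = TRUE)
  if (!nrow(feats)) feats <- matrix(0, 0, meta$nWavelengths)
  .spectra_set(feats, labs, meta$mode, meta$nWavelengths, meta$nIllum,
               prov, meta$dropped)
}
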