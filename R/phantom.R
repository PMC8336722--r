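## Digital tube phantoms: randomized training-volume sampler, deterministic
## phantom layouts, and rasterization of the tube geometry to voxel
## optical-property maps.
##
## Coordinate convention: the imaging plane is (x, z) with x lateral
## (centered on 0) and z the depth below the illuminated surface, increasing
## downward.  Voxels are squares of side `pitch` (mm); a voxel value refers
## to its center.  The default desk-scale configuration is 2D (a single
## elevation slice); transversal tubes are disks in the plane, longitudinal
## tubes are horizontal bands.

#' VoxelPhantom: voxel optical-property maps with tube labels
#'
#' Per-wavelength absorption and reduced-scattering maps of a digital tube
#' phantom, together with the tube label mask and the per-tube ground-truth
#' saturation.
#'
#' @slot pitch Voxel pitch in mm.
#' @slot extent Physical extent c(lateral, depth) in mm.
#' @slot wavelengths Wavelength grid in nm.
#' @slot mua Absorption array `[nz, nx, n_wavelengths]` in 1/cm.
#' @slot musp Reduced-scattering array `[nz, nx, n_wavelengths]` in 1/cm.
#' @slot labels Integer matrix `[nz, nx]`; 0 = background, k = tube id.
#' @slot tubeSaturation Ground-truth saturation per tube id.
#' @slot background The background \code{ChromophoreMixture} (as list).
#' @slot family Chromophore family, \code{"sulfate"} or \code{"hemoglobin"}.
#' @slot geometry The generating tube geometry (list; see
#'   \code{\link{phantomGeometry}}).
#' @export
setClass("VoxelPhantom",
  representation(pitch = "numeric", extent = "numeric",
                 wavelengths = "numeric", mua = "array", musp = "array",
                 labels = "matrix", tubeSaturation = "numeric",
                 background = "list", family = "character",
                 geometry = "list"))

setValidity("VoxelPhantom", function(object) {
  d <- dim(object@mua)
  if (length(d) != 3L) return("mua must be a 3D array [nz, nx, nw]")
  if (!identical(dim(object@musp), d)) return("musp dims must match mua")
  if (!identical(dim(object@labels), d[1:2]))
    return("labels dims must match the spatial dims of mua")
  if (length(object@wavelengths) != d[3])
    return("wavelength count must match dim 3 of mua")
  if (any(object@mua < 0) || any(object@musp < 0))
    return("optical properties must be nonnegative")
  k <- max(object@labels)
  if (k != length(object@tubeSaturation))
    return("tubeSaturation length must equal the number of tube labels")
  if (k > 0 && !setequal(setdiff(unique(as.vector(object@labels)), 0L), seq_len(k)))
    return("tube label ids must be contiguous 1..K")
  TRUE
})

#' @describeIn VoxelPhantom-class Compact description.
#' @param object A \code{VoxelPhantom}.
#' @export
setMethod("show", "VoxelPhantom", function(object) {
  d <- dim(object@mua)
  cat(sprintf("VoxelPhantom (%s): %d x %d voxels @ %.3g mm, %d wavelengths, %d tubes\n",
              object@family, d[1], d[2], object@pitch, d[3],
              length(object@tubeSaturation)))
})

#' Low-level VoxelPhantom constructor
#'
#' Builds a \code{VoxelPhantom} directly from optical-property arrays; mainly
#' useful for constructing controlled media for forward-engine validation.
#'
#' @param mua,musp 3D arrays `[nz, nx, nw]` in 1/cm (a matrix is promoted to
#'   a single-wavelength array).
#' @param pitch Voxel pitch in mm.
#' @param wavelengths Wavelength grid in nm (length nw).
#' @param labels Integer label matrix (default all background).
#' @param tubeSaturation Saturation per tube id.
#' @param family Chromophore family tag.
#' @param background Background mixture (list), informational.
#' @param geometry Generating geometry (list), informational.
#' @return A validated \code{VoxelPhantom}.
#' @export
voxelPhantom <- function(mua, musp, pitch, wavelengths,
                         labels = NULL, tubeSaturation = numeric(0),
                         family = "sulfate", background = list(),
                         geometry = list()) {
  if (is.matrix(mua)) mua <- array(mua, c(dim(mua), 1L))
  if (is.matrix(musp)) musp <- array(musp, c(dim(musp), 1L))
  if (is.null(labels))
    labels <- matrix(0L, nrow(mua), ncol(mua))
  storage.mode(labels) <- "integer"
  new("VoxelPhantom", pitch = as.numeric(pitch),
      extent = c(ncol(mua), nrow(mua)) * pitch,
      wavelengths = as.numeric(wavelengths),
      mua = mua, musp = musp, labels = labels,
      tubeSaturation = as.numeric(tubeSaturation),
      background = background, family = family, geometry = geometry)
}

#' @name VoxelPhantom-accessors
#' @title Accessors for VoxelPhantom
#' @param x A \code{VoxelPhantom}.
#' @param wavelengthIndex Index into the wavelength grid.
#' @return The requested component.
NULL

#' @rdname VoxelPhantom-accessors
#' @export
absorptionMap <- function(x, wavelengthIndex = 1L) x@mua[, , wavelengthIndex]
#' @rdname VoxelPhantom-accessors
#' @export
scatteringMap <- function(x, wavelengthIndex = 1L) x@musp[, , wavelengthIndex]
#' @rdname VoxelPhantom-accessors
#' @export
labelMap <- function(x) x@labels
#' @rdname VoxelPhantom-accessors
#' @export
tubeSaturations <- function(x) x@tubeSaturation
#' @rdname VoxelPhantom-accessors
#' @export
voxelPitch <- function(x) x@pitch
#' @rdname VoxelPhantom-accessors
#' @export
wavelengths <- function(x) x@wavelengths

#' Tube phantom geometry
#'
#' Pure geometry description prior to rasterization.
#'
#' @param tubes data.frame with columns \code{x}, \code{z} (center, mm),
#'   \code{radius} (mm), \code{saturation} in `[0, 1]`, \code{orientation}
#'   (\code{"across"} = perpendicular to the imaging plane, rasterized as a
#'   disk; \code{"along"} = in-plane, rasterized as a horizontal band) and
#'   \code{halfLength} (mm; only used for \code{"along"}).
#' @param background Background \code{ChromophoreMixture}.
#' @param extent c(lateral, depth) extent in mm.
#' @param pitch Voxel pitch in mm.
#' @param family Chromophore family.
#' @return Object of class \code{"PhantomGeometry"}.
#' @export
phantomGeometry <- function(tubes, background, extent = c(40, 30),
                            pitch = 0.3, family = c("sulfate", "hemoglobin")) {
  family <- match.arg(family)
  stopifnot(inherits(background, "ChromophoreMixture"),
            is.data.frame(tubes))
  if (nrow(tubes)) {
    need <- c("x", "z", "radius", "saturation")
    if (!all(need %in% names(tubes))) stop("tubes lacks required columns")
    if (is.null(tubes$orientation)) tubes$orientation <- "across"
    if (is.null(tubes$halfLength)) tubes$halfLength <- NA_real_
    if (any(tubes$radius <= 0)) stop("tube radius must be > 0")
    if (any(tubes$saturation < 0 | tubes$saturation > 1))
      stop("tube saturation must be in [0, 1]")
    inside <- abs(tubes$x) + tubes$radius <= extent[1] / 2 + 1e-9 &
      tubes$z - tubes$radius >= -1e-9 & tubes$z + tubes$radius <= extent[2] + 1e-9
    if (!all(inside)) stop("tube outside volume bounds")
  }
  structure(list(tubes = tubes, background = background,
                 extent = as.numeric(extent), pitch = as.numeric(pitch),
                 family = family),
            class = "PhantomGeometry")
}

#' Sampler configuration for randomized training volumes
#'
#' Defines the randomized training distribution: two sets of tubes with
#' counts drawn from a discrete uniform distribution U\{3, 9\} each, tube
#' saturation from U(0, 1), background saturation from U(0, 1), background
#' volume fraction from U(0, 3)\%, tube radius 0.4 mm.
#'
#' @param nSets Number of tube sets (default 2).
#' @param tubesPerSet c(min, max) of the per-set discrete uniform count
#'   (default c(3, 9)).
#' @param saturationRange c(min, max) of the tube/background saturation
#'   uniform distribution (default c(0, 1)).
#' @param backgroundVfRange c(min, max) of the background volume fraction
#'   uniform distribution (default c(0, 0.03)).
#' @param tubeRadius Tube radius in mm (default 0.4).
#' @param extent c(lateral, depth) volume extent in mm (default c(32, 14):
#'   wide enough to contain the illumination line array with its beam
#'   tails, deep enough that the boundary is several diffusion lengths
#'   below the deepest tube).
#' @param pitch Voxel pitch in mm (default 0.3).
#' @param depthRange Allowed tube-center depth range in mm (default
#'   c(2, 10), bracketing the depths probed in practice, ~3-8 mm).
#' @param lateralRange Allowed tube-center lateral range in mm (default
#'   c(-9.6, 9.6), the 19.2 mm probe field of view).  \code{NULL} allows
#'   the whole volume minus a one-tube-diameter boundary margin.
#' @param maxRetries Per-tube rejection-resampling budget for overlapping
#'   placements (default 100).
#' @return Object of class \code{"SamplerConfig"}.
#' @export
samplerConfig <- function(nSets = 2L, tubesPerSet = c(3L, 9L),
                          saturationRange = c(0, 1),
                          backgroundVfRange = c(0, 0.03),
                          tubeRadius = 0.4, extent = c(32, 14), pitch = 0.3,
                          depthRange = c(2, 10),
                          lateralRange = c(-9.6, 9.6), maxRetries = 100L) {
  stopifnot(nSets >= 1, length(tubesPerSet) == 2, tubesPerSet[1] >= 1,
            tubesPerSet[1] <= tubesPerSet[2],
            saturationRange[1] <= saturationRange[2],
            saturationRange[1] >= 0, saturationRange[2] <= 1,
            backgroundVfRange[1] <= backgroundVfRange[2],
            backgroundVfRange[1] >= 0, backgroundVfRange[2] <= 1,
            tubeRadius > 0, all(extent > 0), pitch > 0,
            depthRange[1] < depthRange[2], maxRetries >= 1)
  if (!is.null(lateralRange))
    stopifnot(length(lateralRange) == 2, lateralRange[1] < lateralRange[2])
  structure(list(nSets = as.integer(nSets),
                 tubesPerSet = as.integer(tubesPerSet),
                 saturationRange = as.numeric(saturationRange),
                 backgroundVfRange = as.numeric(backgroundVfRange),
                 tubeRadius = as.numeric(tubeRadius),
                 extent = as.numeric(extent), pitch = as.numeric(pitch),
                 depthRange = as.numeric(depthRange),
                 lateralRange = if (is.null(lateralRange)) NULL
                                else as.numeric(lateralRange),
                 maxRetries = as.integer(maxRetries)),
            class = "SamplerConfig")
}

# sample non-overlapping tube centers by rejection
.sample_tubes <- function(cfg) {
  r <- cfg$tubeRadius
  # >= 1 tube diameter clearance between tube edge and lateral boundary
  xmax <- cfg$extent[1] / 2 - 3 * r
  if (xmax <= 0) stop("volume too narrow to place tubes")
  xlim <- if (is.null(cfg$lateralRange)) c(-xmax, xmax)
          else c(max(-xmax, cfg$lateralRange[1]),
                 min(xmax, cfg$lateralRange[2]))
  if (xlim[1] >= xlim[2]) stop("empty lateral placement range")
  n <- sum(sample(seq(cfg$tubesPerSet[1], cfg$tubesPerSet[2]),
                  cfg$nSets, replace = TRUE))
  xs <- numeric(0); zs <- numeric(0)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(cfg$maxRetries)) {
      x <- runif(1, xlim[1], xlim[2])
      z <- runif(1, cfg$depthRange[1], cfg$depthRange[2])
      if (!length(xs) || all((xs - x)^2 + (zs - z)^2 >= (2 * r)^2)) {
        xs <- c(xs, x); zs <- c(zs, z); placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf("could not place tube %d without overlap after %d retries",
                   k, cfg$maxRetries))
  }
  data.frame(x = xs, z = zs, radius = r,
             saturation = runif(n, cfg$saturationRange[1],
                                cfg$saturationRange[2]),
             orientation = "across", halfLength = NA_real_)
}

#' Sample a randomized training volume
#'
#' Draws a random tube phantom from the training distribution defined by a
#' \code{SamplerConfig} and rasterizes it to voxel optical-property maps.
#' Reproducible: the same seed yields a bit-identical phantom.
#'
#' @param cfg A \code{SamplerConfig}.
#' @param seed Integer seed for this volume.
#' @param grid Wavelength grid in nm.
#' @param family Chromophore family of tubes and background.
#' @param scattering Background \code{ScatteringModelParams}.
#' @param endmembers Optional endmember override list.
#' @return A \code{VoxelPhantom}.
#' @export
sampleTrainingVolume <- function(cfg = samplerConfig(), seed = 1L,
                                 grid = defaultWavelengthGrid(),
                                 family = c("sulfate", "hemoglobin"),
                                 scattering = scatteringParams(),
                                 endmembers = NULL) {
  stopifnot(inherits(cfg, "SamplerConfig"))
  family <- match.arg(family)
  .with_seed(seed, {
    tubes <- .sample_tubes(cfg)
    bg <- chromophoreMixture(
      runif(1, cfg$saturationRange[1], cfg$saturationRange[2]),
      runif(1, cfg$backgroundVfRange[1], cfg$backgroundVfRange[2]),
      family)
    geom <- phantomGeometry(tubes, bg, extent = cfg$extent,
                            pitch = cfg$pitch, family = family)
    rasterizeOptics(geom, grid, scattering, endmembers = endmembers)
  })
}

#' Deterministic phantom layouts
#'
#' Digital twins of the three physical phantom layouts:
#' \itemize{
#'   \item \code{"A"}: five single tubes spread laterally at 4 mm depth
#'     (validation layout); requires 5 saturations, one per tube.
#'   \item \code{"B"}: five four-tube arrays (two shallow tubes at 3.5 mm,
#'     two deep at 7.5 mm per array); requires 5 saturations, one per
#'     array (20 tubes total).
#'   \item \code{"C"}: the layout-B array geometry with the imaging plane
#'     rotated by 90 degrees, so tubes run along the plane; one shallow and
#'     one deep longitudinal tube; requires 2 saturations (shallow, deep).
#' }
#' Layout tubes default to the physical tubing inner radius (0.58 mm inner
#' diameter).
#'
#' @param layout \code{"A"}, \code{"B"} or \code{"C"}.
#' @param tubeSaturations Saturations as described above.
#' @param background Background \code{ChromophoreMixture}.
#' @param grid Wavelength grid.
#' @param scattering Background \code{ScatteringModelParams}.
#' @param pitch Voxel pitch in mm.
#' @param extent c(lateral, depth) extent in mm.
#' @param tubeRadius Tube radius in mm (default 0.29 = 0.58 mm inner
#'   diameter).
#' @param endmembers Optional endmember override list.
#' @return A \code{VoxelPhantom}.
#' @export
buildLayout <- function(layout = c("A", "B", "C"), tubeSaturations,
                        background, grid = defaultWavelengthGrid(),
                        scattering = scatteringParams(), pitch = 0.3,
                        extent = c(40, 30), tubeRadius = 0.29,
                        endmembers = NULL) {
  layout <- match.arg(layout)
  s <- as.numeric(tubeSaturations)
  if (any(s < 0 | s > 1)) stop("saturations must be in [0, 1]")
  r <- tubeRadius
  tubes <- switch(layout,
    A = {
      if (length(s) != 5L) stop("layout A needs 5 saturations (one per tube)")
      data.frame(x = seq(-12, 12, by = 6), z = 4, radius = r, saturation = s,
                 orientation = "across", halfLength = NA_real_)
    },
    B = {
      if (length(s) != 5L) stop("layout B needs 5 saturations (one per array)")
      cx <- seq(-13, 13, by = 6.5)
      do.call(rbind, lapply(seq_along(cx), function(i)
        data.frame(x = cx[i] + c(-0.75, 0.75, -0.75, 0.75),
                   z = c(3.5, 3.5, 7.5, 7.5), radius = r, saturation = s[i],
                   orientation = "across", halfLength = NA_real_)))
    },
    C = {
      if (length(s) != 2L)
        stop("layout C needs 2 saturations (shallow tube, deep tube)")
      data.frame(x = 0, z = c(3.5, 7.5), radius = r, saturation = s,
                 orientation = "along", halfLength = 7.5)
    })
  geom <- phantomGeometry(tubes, background, extent = extent, pitch = pitch,
                          family = background$family)
  rasterizeOptics(geom, grid, scattering, endmembers = endmembers)
}

#' Rasterize a phantom geometry to voxel optical-property maps
#'
#' Background absorption is the water spectrum plus the background-mixture
#' absorption; tube absorption is the pure mixture at volume fraction 1
#' (undiluted whole-blood-equivalent solution).  Background reduced
#' scattering follows the power-law scattering model; the tube interior
#' contains no scattering agent, so tube \eqn{\mu_s' = 0}.
#'
#' @param geometry A \code{PhantomGeometry}.
#' @param grid Wavelength grid in nm.
#' @param scattering Background \code{ScatteringModelParams}.
#' @param endmembers Optional endmember override list for the family.
#' @param waterTable Optional water endmember override.
#' @return A \code{VoxelPhantom}.
#' @export
rasterizeOptics <- function(geometry, grid = defaultWavelengthGrid(),
                            scattering = scatteringParams(),
                            endmembers = NULL, waterTable = NULL) {
  stopifnot(inherits(geometry, "PhantomGeometry"))
  grid <- wavelengthGrid(grid)
  h <- geometry$pitch
  nx <- max(1L, as.integer(round(geometry$extent[1] / h)))
  nz <- max(1L, as.integer(round(geometry$extent[2] / h)))
  xc <- (seq_len(nx) - 0.5) * h - geometry$extent[1] / 2
  zc <- (seq_len(nz) - 0.5) * h
  nw <- length(grid)

  if (is.null(endmembers))
    endmembers <- bundledEndmembers(geometry$family, grid)
  water <- if (is.null(waterTable)) bundledEndmembers("water", grid)[[1]]
           else .interp_endmember(waterTable, grid)
  bg_mua <- water$mua +
    mixtureAbsorption(geometry$background, grid, endmembers)
  bg_musp <- reducedScattering(scattering, grid)

  labels <- matrix(0L, nz, nx)
  tubes <- geometry$tubes
  sat <- numeric(0)
  if (nrow(tubes)) {
    Z <- matrix(zc, nz, nx)
    X <- matrix(xc, nz, nx, byrow = TRUE)
    for (k in seq_len(nrow(tubes))) {
      tk <- tubes[k, ]
      inside <- if (identical(tk$orientation, "along"))
        abs(Z - tk$z) <= tk$radius & abs(X - tk$x) <= tk$halfLength
      else
        (X - tk$x)^2 + (Z - tk$z)^2 <= tk$radius^2
      if (any(labels[inside] != 0L))
        stop("overlapping tubes in geometry")
      labels[inside] <- k
    }
    sat <- tubes$saturation
  }

  mua <- array(rep(bg_mua, each = nz * nx), c(nz, nx, nw))
  musp <- array(rep(bg_musp, each = nz * nx), c(nz, nx, nw))
  if (nrow(tubes)) {
    idx <- which(labels != 0L)
    for (w in seq_len(nw)) {
      e1 <- endmembers[[1]]$mua[w]; e0 <- endmembers[[2]]$mua[w]
      tube_mua <- sat * e1 + (1 - sat) * e0
      m <- mua[, , w]; m[idx] <- tube_mua[labels[idx]]; mua[, , w] <- m
      m <- musp[, , w]; m[idx] <- 0; musp[, , w] <- m
    }
  }
  voxelPhantom(mua, musp, pitch = h, wavelengths = grid, labels = labels,
               tubeSaturation = sat, family = geometry$family,
               background = unclass(geometry$background),
               geometry = unclass(geometry))
}
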