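## Desk-scale optical forward engine.  Two interchangeable backends produce
## the fluence phi(x, lambda, i) for each wavelength and illumination
## position on the 2D voxel grid, normalized to unit delivered pulse energy:
##   - a finite-difference solver of the heterogeneous diffusion equation
##     (deterministic; default for dataset generation), and
##   - a compiled voxel Monte Carlo engine (validation backend).
## The absorbed energy is H = phi * mu_a pointwise.
##
## Internal units: geometry in mm, optical coefficients converted from the
## user-facing 1/cm to 1/mm at the engine boundary.

#' @include phantom.R
NULL

#' Illumination geometry
#'
#' A line array of widened beams entering the surface normally.
#'
#' @param nPositions Number of illumination positions (default 4).
#' @param spacing Distance between adjacent beam centers in mm (default 8).
#' @param beamFwhm Beam full-width at half-maximum at the surface in mm
#'   (default 7).
#' @param standoff Water-equivalent gel-pad standoff thickness in mm
#'   (default 18).  Only traversed by the Monte Carlo backend when
#'   \code{useStandoff = TRUE}; the collimated beams cross the clear pad
#'   unchanged, so the default desk-scale configuration launches at the
#'   phantom surface.
#' @param useStandoff Include the standoff layer in Monte Carlo transport.
#' @return Object of class \code{"IlluminationGeometry"}.
#' @export
illuminationGeometry <- function(nPositions = 4L, spacing = 8, beamFwhm = 7,
                                 standoff = 18, useStandoff = FALSE) {
  stopifnot(nPositions >= 1, spacing > 0, beamFwhm > 0, standoff > 0)
  structure(list(nPositions = as.integer(nPositions),
                 spacing = as.numeric(spacing),
                 beamFwhm = as.numeric(beamFwhm),
                 standoff = as.numeric(standoff),
                 useStandoff = isTRUE(useStandoff)),
            class = "IlluminationGeometry")
}

#' Beam center offsets of an illumination geometry
#'
#' Beam centers are laid out symmetrically around the lateral volume center.
#'
#' @param illum An \code{IlluminationGeometry}.
#' @return Numeric vector of lateral beam-center offsets in mm.
#' @export
beamOffsets <- function(illum) {
  stopifnot(inherits(illum, "IlluminationGeometry"))
  (seq_len(illum$nPositions) - (illum$nPositions + 1) / 2) * illum$spacing
}

#' EnergyStack: multi-illumination multispectral absorbed energy
#'
#' Absorbed-energy maps H(x, lambda, i) = phi * mu_a for every wavelength
#' and illumination position, normalized per unit delivered pulse energy.
#'
#' @slot H 4D array `[nz, nx, n_wavelengths, n_positions]`.
#' @slot phantom The source \code{VoxelPhantom}.
#' @slot illumination The \code{IlluminationGeometry} (list).
#' @slot backend \code{"diffusion"} or \code{"mc"}.
#' @slot seed Seed used (MC backend; NA for diffusion).
#' @export
setClass("EnergyStack",
  representation(H = "array", phantom = "VoxelPhantom",
                 illumination = "list", backend = "character",
                 seed = "numeric"))

setValidity("EnergyStack", function(object) {
  d <- dim(object@H)
  if (length(d) != 4L) return("H must be [nz, nx, nw, npos]")
  if (!identical(d[1:3], dim(object@phantom@mua)))
    return("H dims must match the phantom maps")
  if (any(object@H < 0)) return("absorbed energy must be nonnegative")
  TRUE
})

#' @describeIn EnergyStack-class Compact description.
#' @param object An \code{EnergyStack}.
#' @export
setMethod("show", "EnergyStack", function(object) {
  d <- dim(object@H)
  cat(sprintf("EnergyStack (%s backend): %d x %d voxels, %d wavelengths x %d illuminations (%d maps)\n",
              object@backend, d[1], d[2], d[3], d[4], d[3] * d[4]))
})

#' @name EnergyStack-accessors
#' @title Accessors for EnergyStack
#' @param x An \code{EnergyStack}.
#' @param wavelengthIndex,positionIndex Map indices.
#' @return The requested component.
NULL

#' @rdname EnergyStack-accessors
#' @export
energyMap <- function(x, wavelengthIndex = 1L, positionIndex = 1L)
  x@H[, , wavelengthIndex, positionIndex]
#' @rdname EnergyStack-accessors
#' @export
stackPhantom <- function(x) x@phantom
#' @rdname EnergyStack-accessors
#' @export
nIlluminations <- function(x) dim(x@H)[4]

# Gaussian beam source profile over lateral voxel centers, normalized to 1.
.beam_profile <- function(xc, center, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-0.5 * ((xc - center) / sigma)^2)
  if (sum(w) <= 0) stop("beam profile does not intersect the volume")
  w / sum(w)
}

# Assemble the 5-point FD operator of [-div(D grad) + mua] phi = q on the
# cell grid, scaled by h^2, with Robin (extrapolated-boundary) conditions on
# all sides; A = pi/4 gives the 2D extrapolation length (pi/4) l_tr via
# z_b = 2 A D.  D and mua in mm units, h in mm.
.diffusion_matrix <- function(D, mua_mm, h, A = pi / 4) {
  nz <- nrow(D); nx <- ncol(D); n <- nz * nx
  idx <- matrix(seq_len(n), nz, nx)
  hm <- function(a, b) 2 * a * b / (a + b)
  Dv <- hm(D[-nz, , drop = FALSE], D[-1, , drop = FALSE])   # faces below cell
  Dh <- hm(D[, -nx, drop = FALSE], D[, -1, drop = FALSE])   # faces right of cell
  diag_v <- mua_mm * h^2
  # interior couplings
  ii <- c(idx[-nz, ], idx[-1, ], idx[, -nx], idx[, -1])
  jj <- c(idx[-1, ], idx[-nz, ], idx[, -1], idx[, -nx])
  xx <- -c(Dv, Dv, Dh, Dh)
  acc <- matrix(0, nz, nx)
  acc[-nz, ] <- acc[-nz, , drop = FALSE] + Dv
  acc[-1, ]  <- acc[-1, , drop = FALSE] + Dv
  acc[, -nx] <- acc[, -nx, drop = FALSE] + Dh
  acc[, -1]  <- acc[, -1, drop = FALSE] + Dh
  # Robin boundary: outflux per boundary face = phi_c / (2A + h/(2D))
  b <- function(Dcells) Dcells / (0.5 + 2 * A * Dcells / h) # times h, scaled /h
  bt <- matrix(0, nz, nx)
  bt[1, ]  <- bt[1, ] + b(D[1, ])
  bt[nz, ] <- bt[nz, ] + b(D[nz, ])
  bt[, 1]  <- bt[, 1] + b(D[, 1])
  bt[, nx] <- bt[, nx] + b(D[, nx])
  vals <- c(as.vector(diag_v + acc + bt), xx)
  Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                       x = vals, dims = c(n, n), symmetric = FALSE)
}

# cached symbolic Cholesky keyed by grid shape
.chol_solve <- function(A, B) {
  As <- methods::as(Matrix::forceSymmetric(A), "CsparseMatrix")
  key <- paste0("chol_", nrow(As))
  ch <- .milsd_cache[[key]]
  ch <- if (is.null(ch)) Matrix::Cholesky(As, LDL = FALSE, super = TRUE)
        else Matrix::update(ch, As)
  .milsd_cache[[key]] <- ch
  as.matrix(Matrix::solve(ch, B, system = "A"))
}

#' Finite-difference diffusion fluence
#'
#' Deterministic surrogate forward model: solves the heterogeneous diffusion
#' equation \eqn{[\nabla\cdot(D\nabla) - \mu_a]\,\phi = -q} on the voxel
#' grid with extrapolated-boundary (Robin) conditions and a Gaussian beam
#' source of the configured FWHM placed one transport mean free path below
#' the illuminated surface, normalized to unit delivered energy.  The engine
#' operates in 2D, so the dimensionally consistent diffusion coefficient
#' \eqn{D = 1/(2(\mu_a + \mu_s'))} and extrapolation length
#' \eqn{(\pi/4)\, l_{tr}} are used (they match the package's 2D Monte Carlo
#' transport; the familiar 1/3 factor is the 3D form).
#'
#' @param phantom A \code{VoxelPhantom}.
#' @param illum An \code{IlluminationGeometry}.
#' @param positionIndex Illumination position index (1-based).
#' @param wavelengthIndex Wavelength index (1-based).
#' @return Fluence matrix `[nz, nx]` (per unit delivered energy).
#' @export
diffusionFluence <- function(phantom, illum = illuminationGeometry(),
                             positionIndex = 1L, wavelengthIndex = 1L) {
  f <- .diffusion_fluence_multi(phantom, illum, wavelengthIndex)
  f[[positionIndex]]
}

# all illumination positions of one wavelength share a factorization
.diffusion_fluence_multi <- function(phantom, illum, wavelengthIndex) {
  stopifnot(inherits(illum, "IlluminationGeometry"))
  mua <- phantom@mua[, , wavelengthIndex] * 0.1    # 1/mm
  musp <- phantom@musp[, , wavelengthIndex] * 0.1  # 1/mm
  if (!all(mua + musp > 0))
    stop("diffusion backend requires mua + musp > 0 everywhere")
  nz <- nrow(mua); nx <- ncol(mua)
  if (nz < 2 || nx < 2) stop("grid too small for the diffusion solver")
  h <- phantom@pitch
  D <- 1 / (2 * (mua + musp))  # 2D transport
  A <- .diffusion_matrix(D, mua, h)
  xc <- (seq_len(nx) - 0.5) * h - phantom@extent[1] / 2
  offs <- beamOffsets(illum)
  B <- matrix(0, nz * nx, length(offs))
  for (i in seq_along(offs)) {
    prof <- .beam_profile(xc, offs[i], illum$beamFwhm)
    # isotropized source depth: one transport mfp below the surface, per column
    z0 <- 1 / (mua[1, ] + musp[1, ])
    iz0 <- pmin(nz, pmax(1L, as.integer(ceiling(z0 / h))))
    B[cbind(iz0 + (seq_len(nx) - 1L) * nz, i)] <-
      B[cbind(iz0 + (seq_len(nx) - 1L) * nz, i)] + prof
  }
  sol <- .chol_solve(A, B)
  if (any(!is.finite(sol)))
    stop("diffusion solve failed: non-finite solution")
  lapply(seq_along(offs), function(i) {
    m <- matrix(sol[, i], nz, nx)
    m[m < 0] <- 0  # clip FD undershoot
    m
  })
}

#' Monte Carlo fluence
#'
#' Unbiased voxel Monte Carlo estimate of the 2D fluence per unit delivered
#' energy.  Photon packets are launched from a Gaussian beam profile of the
#' configured FWHM entering the top surface normally, propagated with
#' exponential free paths against \eqn{\mu_s = \mu_s'/(1-g)} (default
#' anisotropy g = 0.9), scattered by the 2D Henyey-Greenstein phase
#' function, attenuated continuously by absorption along each sub-path
#' (track-length fluence estimator), and terminated when their weight falls
#' below \code{wmin} (the dropped weight is tracked, so the energy balance
#' deposited + escaped + dropped equals the launched weight to floating
#' point precision).
#'
#' @param phantom A \code{VoxelPhantom}.
#' @param illum An \code{IlluminationGeometry}.
#' @param positionIndex Illumination position index.
#' @param wavelengthIndex Wavelength index.
#' @param nPhotons Number of photon packets (>= 1).
#' @param seed Integer RNG seed (deterministic given seed).
#' @param g Scattering anisotropy used to de-reduce \eqn{\mu_s'}.
#' @param wmin Termination weight threshold (default 1e-6).
#' @param pencil If TRUE, ignore the beam FWHM and launch a pencil beam.
#' @return Fluence matrix `[nz, nx]`, with attributes \code{"deposited"},
#'   \code{"escaped"}, \code{"dropped"} (fractions of launched weight).
#' @export
mcFluence <- function(phantom, illum = illuminationGeometry(),
                      positionIndex = 1L, wavelengthIndex = 1L,
                      nPhotons = 1e6, seed = 1L, g = 0.9, wmin = 1e-6,
                      pencil = FALSE) {
  stopifnot(inherits(illum, "IlluminationGeometry"), nPhotons >= 1)
  mua <- phantom@mua[, , wavelengthIndex] * 0.1
  musp <- phantom@musp[, , wavelengthIndex] * 0.1
  if (!length(mua)) stop("zero-size grid")
  if (illum$useStandoff) {
    # prepend a water-equivalent clear layer; collimated beams cross it
    nzs <- as.integer(round(illum$standoff / phantom@pitch))
    wmua <- .interp_endmember(bundledEndmembers("water",
              phantom@wavelengths)[[1]],
              phantom@wavelengths)$mua[wavelengthIndex] * 0.1
    mua <- rbind(matrix(wmua, nzs, ncol(mua)), mua)
    musp <- rbind(matrix(0, nzs, ncol(musp)), musp)
  }
  sigma <- if (pencil) 0 else illum$beamFwhm / (2 * sqrt(2 * log(2)))
  x0 <- beamOffsets(illum)[positionIndex]
  res <- mc_fluence_cpp(mua, musp, g, phantom@pitch, x0, sigma,
                        as.integer(nPhotons), as.integer(seed), wmin)
  flu <- res$fluence
  if (illum$useStandoff) flu <- flu[-seq_len(nrow(flu) - nrow(phantom@labels)), ,
                                    drop = FALSE]
  structure(flu, deposited = res$deposited, escaped = res$escaped,
            dropped = res$dropped)
}

#' Simulate a multi-illumination multispectral absorbed-energy stack
#'
#' Runs the forward engine for every wavelength and illumination position
#' and forms the absorbed energy \eqn{H = \phi \cdot \mu_a} pointwise, each
#' map normalized to unit delivered pulse energy.
#'
#' @param phantom A \code{VoxelPhantom}.
#' @param illum An \code{IlluminationGeometry}.
#' @param backend \code{"diffusion"} (deterministic, default) or
#'   \code{"mc"}.
#' @param nPhotons Photon budget per (wavelength, position) for the MC
#'   backend.
#' @param seed Base seed for the MC backend.
#' @return An \code{EnergyStack}.
#' @export
simulateStack <- function(phantom, illum = illuminationGeometry(),
                          backend = c("diffusion", "mc"), nPhotons = 1e6,
                          seed = 1L) {
  backend <- match.arg(backend)
  d <- dim(phantom@mua)
  nw <- d[3]; np <- illum$nPositions
  H <- array(0, c(d[1], d[2], nw, np))
  for (w in seq_len(nw)) {
    if (backend == "diffusion") {
      flu <- .diffusion_fluence_multi(phantom, illum, w)
      for (i in seq_len(np))
        H[, , w, i] <- flu[[i]] * phantom@mua[, , w]
    } else {
      for (i in seq_len(np)) {
        flu <- mcFluence(phantom, illum, i, w, nPhotons = nPhotons,
                         seed = .child_seed(seed, 17L, w * 100L + i))
        H[, , w, i] <- flu * phantom@mua[, , w]
      }
    }
  }
  new("EnergyStack", H = H, phantom = phantom, illumination = unclass(illum),
      backend = backend,
      seed = if (backend == "mc") as.numeric(seed) else NA_real_)
}
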