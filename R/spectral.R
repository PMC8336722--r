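## Chromophore spectral models: wavelength grids, endmember absorption
## spectra, saturation/volume-fraction mixture algebra, and the power-law
## reduced-scattering model with its least-squares fit.

#' Default illumination wavelength grid
#'
#' The standard acquisition grid: 16 equidistant wavelengths from 680 to
#' 980 nm in 20 nm steps.
#'
#' @return Numeric vector of 16 wavelengths in nm.
#' @export
#' @examples
#' defaultWavelengthGrid()
defaultWavelengthGrid <- function() seq(680, 980, by = 20)

#' Validate a wavelength grid
#'
#' @param values Numeric vector of wavelengths in nm, strictly increasing and
#'   positive.
#' @return The validated numeric vector (invisibly the same object).
#' @export
wavelengthGrid <- function(values = defaultWavelengthGrid()) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values))
    stop("wavelength grid must be a non-empty numeric vector")
  if (any(values <= 0)) stop("wavelengths must be positive")
  if (is.unsorted(values, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  values
}

#' Endmember absorption spectrum
#'
#' A named absorption coefficient spectrum at the whole-blood-equivalent
#' reference concentration of the chromophore.
#'
#' @param name Identifier, e.g. \code{"HbO2"} or \code{"CuSO4"}.
#' @param wavelengths Wavelength grid in nm.
#' @param mua Absorption coefficients in 1/cm, same length as
#'   \code{wavelengths}, nonnegative.
#' @return An object of class \code{"EndmemberSpectrum"} (a validated list).
#' @export
endmemberSpectrum <- function(name, wavelengths, mua) {
  wavelengths <- wavelengthGrid(wavelengths)
  mua <- as.numeric(mua)
  if (length(mua) != length(wavelengths))
    stop("mua and wavelengths must have the same length")
  if (any(!is.finite(mua)) || any(mua < 0))
    stop("mua must be finite and nonnegative")
  structure(list(name = as.character(name), wavelengths = wavelengths,
                 mua = mua),
            class = "EndmemberSpectrum")
}

#' @export
print.EndmemberSpectrum <- function(x, ...) {
  cat(sprintf("EndmemberSpectrum '%s': %d wavelengths %g-%g nm, mu_a %g-%g /cm\n",
              x$name, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), min(x$mua), max(x$mua)))
  invisible(x)
}

#' Read a two-column endmember table
#'
#' Plain-text table with two columns (wavelength in nm, absorption
#' coefficient in 1/cm); lines starting with \code{#} are comments.
#' Wavelengths must be strictly increasing.
#'
#' @param path File path.
#' @param name Name for the resulting endmember.
#' @return An \code{EndmemberSpectrum} on the tabulated grid.
#' @export
readEndmemberTable <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("wavelength", "mua"))
  endmemberSpectrum(name, tab$wavelength, tab$mua)
}

# interpolate an endmember onto a target grid; error outside tabulated range
.interp_endmember <- function(em, grid) {
  grid <- wavelengthGrid(grid)
  rng <- range(em$wavelengths)
  if (min(grid) < rng[1] || max(grid) > rng[2])
    stop(sprintf(
      "requested wavelengths %g-%g nm outside the tabulated range %g-%g nm of '%s'",
      min(grid), max(grid), rng[1], rng[2], em$name))
  mua <- if (all(grid %in% em$wavelengths))
    em$mua[match(grid, em$wavelengths)]
  else
    stats::approx(em$wavelengths, em$mua, xout = grid)$y
  endmemberSpectrum(em$name, grid, mua)
}

# Parametric approximation of the aqueous sulfate solution spectra at their
# whole-blood-equivalent concentrations, c_wb(CuSO4) = 0.25 M and
# c_wb(NiSO4) = 2.2 M.  The Cu(II) aqua complex has a broad NIR band peaking
# near 810 nm (mimicking HbO2); the Ni(II) spectrum decays across the window
# (mimicking Hb).  The two curves cross once in 680-980 nm, like the
# hemoglobin isosbestic point near 800 nm.  Fixed coefficients; exact
# tabulated values can be supplied via readEndmemberTable() instead.
.sulfate_mua <- function(which, wl) {
  switch(which,
         CuSO4 = 6.0 * exp(-((wl - 810) / 150)^2),
         NiSO4 = 0.9 + 12.6 * exp(-(wl - 660) / 110),
         stop("unknown sulfate"))
}

#' Bundled endmember spectra
#'
#' Returns the bundled endmember absorption spectra for a chromophore
#' family, interpolated onto the requested wavelength grid.
#' \itemize{
#'   \item \code{"hemoglobin"}: HbO2 and Hb at average whole-blood total
#'     hemoglobin concentration 150 g/l (from bundled literature extinction
#'     tables).
#'   \item \code{"sulfate"}: CuSO4 (0.25 M) and NiSO4 (2.2 M)
#'     whole-blood-equivalent solutions, from a documented parametric
#'     approximation of measured spectra.
#'   \item \code{"water"}: pure water (literature table).
#' }
#' The first list element is always the oxygenated-like endmember (HbO2 or
#' CuSO4), the second the deoxygenated-like one (Hb or NiSO4).
#'
#' @param family One of \code{"sulfate"}, \code{"hemoglobin"},
#'   \code{"water"}.
#' @param grid Wavelength grid in nm (default \code{defaultWavelengthGrid()}).
#' @param tables Optional named list of \code{EndmemberSpectrum} overrides
#'   (names among \code{"CuSO4"}, \code{"NiSO4"}, \code{"HbO2"}, \code{"Hb"},
#'   \code{"water"}), e.g. from user-supplied spectrophotometer tables.
#' @return List of \code{EndmemberSpectrum} objects.
#' @export
#' @examples
#' em <- bundledEndmembers("sulfate")
#' em[[1]]$name  # "CuSO4"
bundledEndmembers <- function(family = c("sulfate", "hemoglobin", "water"),
                              grid = defaultWavelengthGrid(),
                              tables = list()) {
  family <- match.arg(family)
  grid <- wavelengthGrid(grid)
  pick <- function(nm, default) {
    em <- if (!is.null(tables[[nm]])) tables[[nm]] else default()
    .interp_endmember(em, grid)
  }
  ext <- function(f, nm) {
    readEndmemberTable(system.file("extdata", f, package = "milsd",
                                   mustWork = TRUE), nm)
  }
  switch(family,
    sulfate = list(
      pick("CuSO4", function()
        endmemberSpectrum("CuSO4", grid, .sulfate_mua("CuSO4", grid))),
      pick("NiSO4", function()
        endmemberSpectrum("NiSO4", grid, .sulfate_mua("NiSO4", grid)))),
    hemoglobin = list(
      pick("HbO2", function() ext("hbo2_mua_wholeblood.tsv", "HbO2")),
      pick("Hb",   function() ext("hb_mua_wholeblood.tsv", "Hb"))),
    water = list(
      pick("water", function() ext("water_mua.tsv", "water"))))
}

#' Chromophore mixture
#'
#' A local chromophore state: the saturation fraction (rCu for the sulfate
#' family, sO2 for hemoglobin) and the volume fraction (SVF or BVF) of the
#' whole-blood-equivalent mixture in the voxel.
#'
#' @param saturation Fraction in `[0, 1]`.
#' @param volumeFraction Fraction in `[0, 1]` (1 = undiluted whole-blood
#'   equivalent, as inside a vessel/tube).
#' @param family \code{"sulfate"} or \code{"hemoglobin"}.
#' @return Object of class \code{"ChromophoreMixture"}.
#' @export
chromophoreMixture <- function(saturation, volumeFraction,
                               family = c("sulfate", "hemoglobin")) {
  family <- match.arg(family)
  saturation <- as.numeric(saturation)
  volumeFraction <- as.numeric(volumeFraction)
  if (length(saturation) != 1L || !is.finite(saturation) ||
      saturation < 0 || saturation > 1)
    stop("saturation must be a single value in [0, 1]")
  if (length(volumeFraction) != 1L || !is.finite(volumeFraction) ||
      volumeFraction < 0 || volumeFraction > 1)
    stop("volumeFraction must be a single value in [0, 1]")
  structure(list(saturation = saturation, volumeFraction = volumeFraction,
                 family = family),
            class = "ChromophoreMixture")
}

#' @export
print.ChromophoreMixture <- function(x, ...) {
  cat(sprintf("ChromophoreMixture (%s): saturation %.3f, volume fraction %.4f\n",
              x$family, x$saturation, x$volumeFraction))
  invisible(x)
}

#' Absorption spectrum of a chromophore mixture
#'
#' Linear mixture algebra: with oxygenated-like endmember E1 and
#' deoxygenated-like endmember E0 at whole-blood-equivalent concentration,
#' the voxel absorption contributed by the mixture is
#' \deqn{\mu_a(\lambda) = v \, [s\, E_1(\lambda) + (1 - s)\, E_0(\lambda)]}
#' with saturation \eqn{s} and volume fraction \eqn{v}.  The result is
#' linear in both \eqn{s} and \eqn{v}.
#'
#' @param mix A \code{ChromophoreMixture}.
#' @param grid Wavelength grid in nm.
#' @param endmembers Optional endmember list (as from
#'   \code{\link{bundledEndmembers}}); defaults to the bundled family
#'   endmembers on \code{grid}.
#' @return Numeric absorption spectrum in 1/cm on \code{grid}.
#' @export
#' @examples
#' bg <- chromophoreMixture(0.5, 0.01, "sulfate")
#' mixtureAbsorption(bg)  # the rCu_bg = 50%, SVF = 1% background construction
mixtureAbsorption <- function(mix, grid = defaultWavelengthGrid(),
                              endmembers = NULL) {
  stopifnot(inherits(mix, "ChromophoreMixture"))
  grid <- wavelengthGrid(grid)
  if (is.null(endmembers)) endmembers <- bundledEndmembers(mix$family, grid)
  e1 <- .interp_endmember(endmembers[[1]], grid)$mua
  e0 <- .interp_endmember(endmembers[[2]], grid)$mua
  mix$volumeFraction * (mix$saturation * e1 + (1 - mix$saturation) * e0)
}

#' Reduced-scattering model parameters
#'
#' Parameters of the generic tissue scattering model
#' \deqn{\mu_s'(\lambda) = \mu_{s,500}' \left[ f_{ray} (\lambda/500)^{-4}
#'   + (1 - f_{ray}) (\lambda/500)^{-b_{mie}} \right]}
#' The defaults are the model's nominal values for a 1.5% fat-emulsion
#' tissue-mimicking background: \eqn{\mu_{s,500}' = 42.4} 1/cm,
#' \eqn{f_{ray} = 0.62}, \eqn{b_{mie} = 1.0}.
#'
#' @param mus500 Reduced scattering at 500 nm, 1/cm, positive.
#' @param fray Rayleigh fraction in `[0, 1]`.
#' @param bmie Mie scatter power (dimensionless).
#' @return Object of class \code{"ScatteringModelParams"}.
#' @export
scatteringParams <- function(mus500 = 42.4, fray = 0.62, bmie = 1.0) {
  mus500 <- as.numeric(mus500); fray <- as.numeric(fray); bmie <- as.numeric(bmie)
  if (!is.finite(mus500) || mus500 <= 0) stop("mus500 must be > 0")
  if (!is.finite(fray) || fray < 0 || fray > 1) stop("fray must be in [0, 1]")
  if (!is.finite(bmie)) stop("bmie must be finite")
  structure(list(mus500 = mus500, fray = fray, bmie = bmie),
            class = "ScatteringModelParams")
}

#' @export
print.ScatteringModelParams <- function(x, ...) {
  cat(sprintf("ScatteringModelParams: mus500' = %.3g /cm, f_ray = %.3g, b_mie = %.3g\n",
              x$mus500, x$fray, x$bmie))
  invisible(x)
}

#' Evaluate the reduced-scattering model
#'
#' @param params A \code{ScatteringModelParams}.
#' @param wavelengths Wavelengths in nm (positive).
#' @return Reduced scattering coefficients in 1/cm.
#' @export
#' @examples
#' reducedScattering(scatteringParams(), 750)  # ~15.9 /cm
reducedScattering <- function(params, wavelengths = defaultWavelengthGrid()) {
  stopifnot(inherits(params, "ScatteringModelParams"))
  wavelengths <- as.numeric(wavelengths)
  if (any(!is.finite(wavelengths)) || any(wavelengths <= 0))
    stop("wavelengths must be positive")
  r <- wavelengths / 500
  params$mus500 * (params$fray * r^-4 + (1 - params$fray) * r^-params$bmie)
}

#' Fit the reduced-scattering model to (wavelength, mus') samples
#'
#' Least-squares fit of the power-law scattering model to measured
#' \eqn{(\lambda, \mu_s')} tuples, as used to extend time-resolved
#' spectroscopy results of the phantom background medium over the full
#' acquisition band.
#'
#' @param wavelengths Sample wavelengths in nm (at least 3 samples over at
#'   least 2 distinct wavelengths).
#' @param musp Measured reduced scattering in 1/cm.
#' @param init Initial-guess \code{ScatteringModelParams}.
#' @return Fitted \code{ScatteringModelParams} whose residual norm does not
#'   exceed the residual norm at \code{init}.
#' @export
fitScatteringModel <- function(wavelengths, musp, init = scatteringParams()) {
  stopifnot(inherits(init, "ScatteringModelParams"))
  wavelengths <- as.numeric(wavelengths); musp <- as.numeric(musp)
  if (length(wavelengths) != length(musp))
    stop("wavelengths and musp must have the same length")
  if (length(wavelengths) < 3L)
    stop("need at least 3 samples")
  if (length(unique(wavelengths)) < 2L)
    stop("degenerate samples: need at least 2 distinct wavelengths")
  if (any(wavelengths <= 0)) stop("wavelengths must be positive")
  dat <- data.frame(w = wavelengths, y = musp)
  fit <- minpack.lm::nlsLM(
    y ~ m5 * (f * (w / 500)^-4 + (1 - f) * (w / 500)^-b),
    data = dat,
    start = list(m5 = init$mus500, f = init$fray, b = init$bmie),
    lower = c(1e-9, 0, -10), upper = c(Inf, 1, 10),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 500))
  cf <- stats::coef(fit)
  out <- scatteringParams(cf[["m5"]], cf[["f"]], cf[["b"]])
  rss <- function(p) sum((musp - reducedScattering(p, wavelengths))^2)
  if (rss(out) > rss(init) + 1e-12) init else out
}
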