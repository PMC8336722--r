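## End-to-end experiment orchestration: dataset generation, estimator
## training, LU baseline, evaluation and reporting, with keyed RNG streams
## for full reproducibility from (config, master seed).

#' Experiment configuration
#'
#' Defines a complete in-silico decoloring experiment.  The defaults are
#' the desk-scale reproduction protocol: 300 training and 100 test volumes
#' drawn from the randomized tube sampler, 16 wavelengths, 4 illumination
#' positions, deterministic diffusion forward backend, and the random
#' forest estimators in both MI-LSD and LSD modes.
#'
#' @param family \code{"sulfate"} (rCu) or \code{"hemoglobin"} (sO2).
#' @param nTrain,nTest Volume counts (>= 1).
#' @param sampler A \code{SamplerConfig}.
#' @param illum An \code{IlluminationGeometry}.
#' @param grid Wavelength grid in nm.
#' @param scattering Background \code{ScatteringModelParams}.
#' @param backend \code{"diffusion"} or \code{"mc"}.
#' @param nPhotons MC photon budget per map (MC backend only).
#' @param estimators List of \code{EstimatorConfig}s to train.
#' @param seed Master seed; all stage RNG streams are derived from it.
#' @param outDir Optional output directory for artifacts and the manifest.
#' @param verbose Print stage progress.
#' @return Object of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(family = c("sulfate", "hemoglobin"),
                             nTrain = 300L, nTest = 100L,
                             sampler = samplerConfig(),
                             illum = illuminationGeometry(),
                             grid = defaultWavelengthGrid(),
                             scattering = scatteringParams(),
                             backend = c("diffusion", "mc"),
                             nPhotons = 1e6,
                             estimators = list(
                               estimatorConfig("rf", "milsd"),
                               estimatorConfig("rf", "lsd")),
                             seed = 1L, outDir = NULL, verbose = FALSE) {
  family <- match.arg(family); backend <- match.arg(backend)
  stopifnot(nTrain >= 1, nTest >= 1, inherits(sampler, "SamplerConfig"),
            inherits(illum, "IlluminationGeometry"))
  structure(list(family = family, nTrain = as.integer(nTrain),
                 nTest = as.integer(nTest), sampler = sampler,
                 illum = illum, grid = wavelengthGrid(grid),
                 scattering = scattering, backend = backend,
                 nPhotons = as.numeric(nPhotons), estimators = estimators,
                 seed = as.integer(seed), outDir = outDir,
                 verbose = isTRUE(verbose)),
            class = "ExperimentConfig")
}

# simulate a batch of volumes and extract both feature modes
.simulate_split <- function(cfg, n, stage, mirror) {
  milsd <- vector("list", n); lsd <- vector("list", n)
  for (v in seq_len(n)) {
    ph <- sampleTrainingVolume(cfg$sampler,
                               seed = .child_seed(cfg$seed, stage, v),
                               grid = cfg$grid, family = cfg$family,
                               scattering = cfg$scattering)
    st <- simulateStack(ph, cfg$illum, backend = cfg$backend,
                        nPhotons = cfg$nPhotons,
                        seed = .child_seed(cfg$seed, stage + 1L, v))
    milsd[[v]] <- extractSamples(st, "milsd", augmentMirror = mirror,
                                 volumeId = v)
    lsd[[v]] <- extractSamples(st, "lsd", volumeId = v)
    if (cfg$verbose && v %% 25L == 0L)
      message(sprintf("  stage %d: volume %d / %d", stage, v, n))
  }
  list(milsd = bindSpectraSets(milsd), lsd = bindSpectraSets(lsd))
}

#' Run a complete in-silico decoloring experiment
#'
#' Generates training and held-out test volumes from the randomized tube
#' sampler, simulates their multi-illumination multispectral
#' absorbed-energy stacks, extracts L1-normalized tube-voxel samples
#' (mirror augmentation on the MI-LSD training set), trains the configured
#' estimators, evaluates them and the linear-unmixing baseline on the test
#' set, and returns the error summaries.
#'
#' @param cfg An \code{ExperimentConfig}.
#' @return List with elements
#'   \itemize{
#'     \item \code{summaries}: named list of \code{ErrorStats}
#'       (\code{"rf.milsd.insilico"}, ..., \code{"lu..insilico"}),
#'     \item \code{table}: the \code{\link{reportTable}} data.frame,
#'     \item \code{models}: the fitted \code{SaturationEstimator}s,
#'     \item \code{predictions}: per-method estimate vectors and the test
#'       truths,
#'     \item \code{info}: sample counts, dropped-sample counts, timings and
#'       the manifest (config fingerprint + seeds).
#'   }
#'   If \code{cfg$outDir} is set, the table (TSV), summaries and manifest
#'   (JSON) are also written there.
#' @export
runExperiment <- function(cfg = experimentConfig()) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  t0 <- proc.time()[["elapsed"]]
  if (cfg$verbose) message("simulating training volumes ...")
  train <- .simulate_split(cfg, cfg$nTrain, stage = 100L, mirror = TRUE)
  if (cfg$verbose) message("simulating test volumes ...")
  test <- .simulate_split(cfg, cfg$nTest, stage = 300L, mirror = FALSE)
  tsim <- proc.time()[["elapsed"]] - t0

  truths <- saturationLabels(test$milsd)
  truths_lsd <- saturationLabels(test$lsd)
  models <- list(); summaries <- list(); predictions <- list()
  for (ecfg in cfg$estimators) {
    key <- paste(ecfg$model, ecfg$mode, sep = ".")
    if (cfg$verbose) message("training ", key, " ...")
    est <- trainEstimator(train[[ecfg$mode]], ecfg)
    models[[key]] <- est
    p <- predictSaturation(est, test[[ecfg$mode]])
    tt <- if (ecfg$mode == "milsd") truths else truths_lsd
    summaries[[paste0(key, ".insilico")]] <- summarizeErrors(p, tt)
    predictions[[key]] <- as.vector(p)  # drop timing attributes
  }
  # LU baseline on the mean-illumination spectra (model-free)
  em <- bundledEndmembers(cfg$family, cfg$grid)
  plu <- linearUnmixingBatch(featureMatrix(test$lsd), em)
  summaries[["lu..insilico"]] <- summarizeErrors(plu, truths_lsd)
  predictions[["lu"]] <- plu

  tab <- reportTable(summaries)
  info <- list(
    nTrainSamplesMilsd = nrow(featureMatrix(train$milsd)),
    nTrainSamplesLsd = nrow(featureMatrix(train$lsd)),
    nTestSamplesMilsd = nrow(featureMatrix(test$milsd)),
    nTestSamplesLsd = nrow(featureMatrix(test$lsd)),
    droppedTrain = droppedSamples(train$milsd),
    droppedTest = droppedSamples(test$milsd),
    simulationSeconds = tsim,
    totalSeconds = proc.time()[["elapsed"]] - t0,
    manifest = .experiment_manifest(cfg))
  res <- list(summaries = summaries, table = tab, models = models,
              predictions = c(predictions,
                              list(truthMilsd = truths, truthLsd = truths_lsd)),
              info = info)
  if (!is.null(cfg$outDir)) .write_experiment(res, cfg)
  res
}

.experiment_manifest <- function(cfg) {
  list(package = "milsd",
       version = as.character(utils::packageVersion("milsd")),
       family = cfg$family, nTrain = cfg$nTrain, nTest = cfg$nTest,
       backend = cfg$backend, seed = cfg$seed,
       grid = cfg$grid,
       sampler = unclass(cfg$sampler), illumination = unclass(cfg$illum),
       scattering = unclass(cfg$scattering),
       estimators = lapply(cfg$estimators, unclass))
}

.write_experiment <- function(res, cfg) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  writeLines(formatReportTable(res$table),
             file.path(cfg$outDir, "summaries.tsv"), sep = "")
  jsonlite::write_json(
    c(res$info["manifest"],
      list(summaries = lapply(res$summaries, function(s)
        list(signed = as.list(signedStats(s)),
             absolute = as.list(absoluteStats(s)), n = sampleCount(s)))),
      res$info[setdiff(names(res$info), "manifest")]),
    file.path(cfg$outDir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (key in names(res$models))
    saveEstimator(res$models[[key]],
                  file.path(cfg$outDir, paste0("model_", gsub("\\.", "_", key),
                                               ".rds")))
  invisible(NULL)
}

#' Evaluate trained models on out-of-distribution longitudinal scenes
#'
#' Builds layout-C scenes (tubes oriented along the imaging plane, unlike
#' the transversal-only training distribution), simulates them with the
#' configured backend, and evaluates the supplied trained models plus the
#' LU baseline.  The expected ordering (OOD error at or above
#' in-distribution error) is reported, not asserted.
#'
#' @param cfg The \code{ExperimentConfig} used for training.
#' @param models Named list of \code{SaturationEstimator}s from
#'   \code{\link{runExperiment}}.
#' @param tubeSaturations Saturations of the scanned tubes (one scene per
#'   value, containing a shallow and a deep longitudinal tube at that
#'   saturation).
#' @param background Background mixture of the scenes.
#' @param inDistribution Optional named list of in-distribution
#'   \code{ErrorStats} to compare against.
#' @return List: \code{summaries} per model (+ \code{"lu"}),
#'   \code{comparison} data.frame of OOD vs in-distribution median absolute
#'   errors (when supplied), \code{nScenes}.
#' @export
runOodExperiment <- function(cfg, models,
                             tubeSaturations = c(0, 0.25, 0.5, 0.75, 1),
                             background = NULL, inDistribution = NULL) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  if (!length(models)) stop("missing models: train with runExperiment first")
  if (is.null(background))
    background <- chromophoreMixture(0.5, 0.01, cfg$family)
  sets_milsd <- list(); sets_lsd <- list()
  for (i in seq_along(tubeSaturations)) {
    s <- tubeSaturations[i]
    ph <- buildLayout("C", c(s, s), background, grid = cfg$grid,
                      scattering = cfg$scattering,
                      pitch = cfg$sampler$pitch, extent = cfg$sampler$extent)
    st <- simulateStack(ph, cfg$illum, backend = cfg$backend,
                        nPhotons = cfg$nPhotons,
                        seed = .child_seed(cfg$seed, 500L, i))
    sets_milsd[[i]] <- extractSamples(st, "milsd", volumeId = i)
    sets_lsd[[i]] <- extractSamples(st, "lsd", volumeId = i)
  }
  milsd <- bindSpectraSets(sets_milsd); lsd <- bindSpectraSets(sets_lsd)
  summaries <- list()
  for (key in names(models)) {
    est <- models[[key]]
    set <- if (est@mode == "milsd") milsd else lsd
    p <- predictSaturation(est, set)
    summaries[[paste0(key, ".ood")]] <-
      summarizeErrors(p, saturationLabels(set))
  }
  em <- bundledEndmembers(cfg$family, cfg$grid)
  summaries[["lu..ood"]] <- summarizeErrors(
    linearUnmixingBatch(featureMatrix(lsd), em), saturationLabels(lsd))
  comparison <- NULL
  if (!is.null(inDistribution)) {
    keys <- sub("\\.insilico$", "", names(inDistribution))
    comparison <- data.frame(
      method = keys,
      inDistributionQ2 = vapply(inDistribution, function(s)
        absoluteStats(s)[["q2"]], numeric(1)),
      oodQ2 = vapply(keys, function(k) {
        s <- summaries[[paste0(k, ".ood")]]
        if (is.null(s)) NA_real_ else absoluteStats(s)[["q2"]]
      }, numeric(1)))
    rownames(comparison) <- NULL
  }
  list(summaries = summaries, comparison = comparison,
       nScenes = length(tubeSaturations))
}
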