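## Saturation regressors for learned spectral decoloring: random forest
## (ranger backend) and a feedforward neural network (implemented in
## R/nn.R).  Both map normalized spectra features to saturation in [0, 1].

#' Estimator configuration
#'
#' Hyperparameters of the decoloring regressors.  Defaults follow the
#' reference configuration: the random forest uses 100 trees with maximum
#' depth 30; the neural network has four hidden layers of twice the input
#' width (32 for LSD, 128 for MI-LSD), leaky-ReLU activations, no dropout,
#' 100 epochs with batch size 1e5 (capped at the dataset size) and the
#' learning-rate schedule \eqn{lr(e) = 10^{-2} \cdot 0.9^{e/2}} (epoch
#' \eqn{e} counted from 0), trained with plain SGD on a mean squared error
#' loss.
#'
#' @param model \code{"rf"} or \code{"nn"}.
#' @param mode \code{"milsd"} or \code{"lsd"}.
#' @param nTrees,maxDepth Random forest size.
#' @param mtry Candidate features per split; \code{NULL} (default) uses all
#'   features, the scikit-learn regression-forest default the reference
#'   configuration is based on.
#' @param minNodeSize Minimal terminal node size (default 1, again the
#'   reference regression-forest default).
#' @param hiddenLayers Number of hidden layers.
#' @param widthFactor Hidden width as a multiple of the input width.
#' @param dropout Dropout probability during NN training (default 0).
#' @param epochs,batchSize,lr0,lrDecayPerEpoch NN training schedule;
#'   \code{lr(e) = lr0 * lrDecayPerEpoch^e} with
#'   \code{lrDecayPerEpoch = 0.9^(1/2)} reproducing \eqn{0.9^{e/2}}.
#' @param leakySlope Negative-side slope of the leaky ReLU.
#' @param seed Training seed (both models are deterministic given it).
#' @return Object of class \code{"EstimatorConfig"}.
#' @export
estimatorConfig <- function(model = c("rf", "nn"),
                            mode = c("milsd", "lsd"),
                            nTrees = 100L, maxDepth = 30L,
                            mtry = NULL, minNodeSize = 1L,
                            hiddenLayers = 4L, widthFactor = 2L,
                            dropout = 0, epochs = 100L, batchSize = 1e5,
                            lr0 = 1e-2, lrDecayPerEpoch = 0.9^(1 / 2),
                            leakySlope = 0.01, seed = 1L) {
  model <- match.arg(model); mode <- match.arg(mode)
  stopifnot(nTrees >= 1, maxDepth >= 1, hiddenLayers >= 1, widthFactor >= 1,
            dropout >= 0, dropout < 1, epochs >= 1, batchSize >= 1, lr0 > 0)
  structure(list(model = model, mode = mode, nTrees = as.integer(nTrees),
                 maxDepth = as.integer(maxDepth),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 minNodeSize = as.integer(minNodeSize),
                 hiddenLayers = as.integer(hiddenLayers),
                 widthFactor = as.integer(widthFactor),
                 dropout = as.numeric(dropout), epochs = as.integer(epochs),
                 batchSize = as.numeric(batchSize), lr0 = as.numeric(lr0),
                 lrDecayPerEpoch = as.numeric(lrDecayPerEpoch),
                 leakySlope = as.numeric(leakySlope),
                 seed = as.integer(seed)),
            class = "EstimatorConfig")
}

#' SaturationEstimator: a fitted decoloring regressor
#'
#' @slot kind \code{"rf"} or \code{"nn"}.
#' @slot mode \code{"milsd"} or \code{"lsd"}.
#' @slot inputWidth Expected feature width.
#' @slot fit Backend fit object (ranger forest or MLP weight list).
#' @slot config The \code{EstimatorConfig} used (list).
#' @slot trainingInfo List: sample count, loss curve (NN), timing.
#' @export
setClass("SaturationEstimator",
  representation(kind = "character", mode = "character",
                 inputWidth = "integer", fit = "list", config = "list",
                 trainingInfo = "list"))

#' @describeIn SaturationEstimator-class Compact description.
#' @param object A \code{SaturationEstimator}.
#' @export
setMethod("show", "SaturationEstimator", function(object) {
  cat(sprintf("SaturationEstimator: %s / %s, input width %d, trained on %d samples\n",
              object@kind, object@mode, object@inputWidth,
              object@trainingInfo$nSamples %||% NA_integer_))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Network layer widths of an estimator configuration
#'
#' @param cfg An \code{EstimatorConfig} with \code{model = "nn"}.
#' @param inputWidth Feature width (16 for LSD, 64 for MI-LSD on the
#'   default grid).
#' @return Integer vector of layer widths, input through output.
#' @export
nnLayerWidths <- function(cfg, inputWidth) {
  c(inputWidth, rep(cfg$widthFactor * inputWidth, cfg$hiddenLayers), 1L)
}

#' Train a decoloring estimator
#'
#' @param train A \code{SpectraSet} of training samples.
#' @param cfg An \code{EstimatorConfig}; its \code{mode} must match the
#'   spectra set.
#' @return A \code{SaturationEstimator}.
#' @export
trainEstimator <- function(train, cfg = estimatorConfig()) {
  stopifnot(is(train, "SpectraSet"), inherits(cfg, "EstimatorConfig"))
  if (cfg$mode != train@mode)
    stop(sprintf("config mode '%s' does not match spectra mode '%s'",
                 cfg$mode, train@mode))
  X <- featureMatrix(train); y <- saturationLabels(train)
  if (!nrow(X)) stop("empty training set")
  t0 <- proc.time()[["elapsed"]]
  if (cfg$model == "rf") {
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    fit <- ranger::ranger(x = X, y = y, num.trees = cfg$nTrees,
                          max.depth = cfg$maxDepth,
                          mtry = if (is.null(cfg$mtry)) ncol(X)
                                 else min(cfg$mtry, ncol(X)),
                          min.node.size = cfg$minNodeSize,
                          seed = cfg$seed,
                          num.threads = 1L, verbose = FALSE)
    info <- list(nSamples = nrow(X), oobMse = fit$prediction.error)
    fitlist <- list(forest = fit)
  } else {
    fit <- .train_mlp(X, y, cfg)
    info <- list(nSamples = nrow(X), loss = fit$loss)
    fitlist <- list(mlp = fit)
  }
  info$seconds <- proc.time()[["elapsed"]] - t0
  new("SaturationEstimator", kind = cfg$model, mode = cfg$mode,
      inputWidth = ncol(X), fit = fitlist, config = unclass(cfg),
      trainingInfo = info)
}

#' Predict saturations
#'
#' Vectorized prediction; estimates are clipped to `[0, 1]`.  The elapsed
#' time and throughput are attached as attributes \code{"seconds"} and
#' \code{"samplesPerSecond"}.
#'
#' @param estimator A \code{SaturationEstimator}.
#' @param samples A \code{SpectraSet} or a feature matrix of matching width.
#' @return Numeric vector of saturation estimates in `[0, 1]`.
#' @export
predictSaturation <- function(estimator, samples) {
  stopifnot(is(estimator, "SaturationEstimator"))
  X <- if (is(samples, "SpectraSet")) featureMatrix(samples)
       else as.matrix(samples)
  if (!nrow(X)) return(numeric(0))
  if (ncol(X) != estimator@inputWidth)
    stop(sprintf("feature width %d does not match the estimator input width %d",
                 ncol(X), estimator@inputWidth))
  t0 <- proc.time()[["elapsed"]]
  p <- if (estimator@kind == "rf") {
    if (is.null(estimator@fit$forest)) stop("unfitted estimator")
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    stats::predict(estimator@fit$forest, data = X,
                   num.threads = 1L)$predictions
  } else {
    if (is.null(estimator@fit$mlp)) stop("unfitted estimator")
    as.vector(.mlp_forward(estimator@fit$mlp, X)$out)
  }
  dt <- proc.time()[["elapsed"]] - t0
  structure(pmin(1, pmax(0, p)), seconds = dt,
            samplesPerSecond = nrow(X) / max(dt, .Machine$double.eps))
}

#' Persist / restore a fitted estimator
#'
#' Stores the estimator together with its configuration, seed and a hash of
#' the training-set dimensions for traceability.
#'
#' @param estimator A \code{SaturationEstimator}.
#' @param path File path (.rds).
#' @return \code{saveEstimator}: the path, invisibly.
#' @export
saveEstimator <- function(estimator, path) {
  stopifnot(is(estimator, "SaturationEstimator"))
  saveRDS(estimator, path)
  invisible(path)
}

#' @rdname saveEstimator
#' @export
loadEstimator <- function(path) {
  est <- readRDS(path)
  stopifnot(is(est, "SaturationEstimator"))
  est
}
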