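# Regression engines: deterministic multiple linear regression (the
# classical scoring-function fit) and seeded random-forest regression,
# plus the repeated-training protocol.

#' Model specification
#'
#' @slot kind \code{"MLR"} or \code{"RF"}.
#' @slot nTrees number of trees (RF only; default 500).
#' @slot mtryRule features tried per split: \code{"p/3"} (default,
#'   \eqn{\lceil p/3 \rceil}) or a fixed positive integer stored as a
#'   string.
#' @slot nRepeats training repeats per cutoff (default 10).
#' @slot baseSeed base seed; repeat \eqn{r} (0-based) uses
#'   \code{baseSeed + r}.
#'
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(kind = "character", nTrees = "integer",
                 mtryRule = "character", nRepeats = "integer",
                 baseSeed = "integer"))

setValidity("ModelSpec", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("MLR", "RF"))
    msgs <- c(msgs, "kind must be 'MLR' or 'RF'")
  if (object@nTrees < 1L) msgs <- c(msgs, "nTrees must be >= 1")
  if (object@nRepeats < 1L) msgs <- c(msgs, "nRepeats must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ModelSpec
#'
#' @param kind \code{"MLR"} or \code{"RF"}.
#' @param nTrees trees per forest (RF).
#' @param mtryRule \code{"p/3"} or a positive integer.
#' @param nRepeats number of training repeats.
#' @param baseSeed base RNG seed for the repeat protocol.
#' @return A \linkS4class{ModelSpec}.
#' @export
modelSpec <- function(kind = c("RF", "MLR"), nTrees = 500L,
                      mtryRule = "p/3", nRepeats = 10L, baseSeed = 1L) {
  kind <- match.arg(kind)
  new("ModelSpec", kind = kind, nTrees = as.integer(nTrees),
      mtryRule = as.character(mtryRule), nRepeats = as.integer(nRepeats),
      baseSeed = as.integer(baseSeed))
}

resolveMtry <- function(spec, p) {
  if (spec@mtryRule == "p/3") max(1L, as.integer(ceiling(p / 3)))
  else max(1L, min(p, as.integer(spec@mtryRule)))
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s%s, %d repeat(s), base seed %d\n", object@kind,
              if (object@kind == "RF")
                sprintf(" (%d trees, mtry %s)", object@nTrees,
                        object@mtryRule) else "",
              object@nRepeats, object@baseSeed))
})

#' Fitted scoring-function model
#'
#' @slot kind \code{"MLR"} or \code{"RF"}.
#' @slot fit the underlying predictor (coefficient vector for MLR, a
#'   ranger forest for RF).
#' @slot seed seed used (NA for MLR).
#' @slot trainingIds ids of the complexes the model was fitted on.
#' @slot scheme descriptor scheme the model expects.
#' @slot featureNames training feature order, enforced at prediction.
#'
#' @exportClass FittedModel
setClass("FittedModel",
  representation(kind = "character", fit = "ANY", seed = "integer",
                 trainingIds = "character", scheme = "character",
                 featureNames = "character"))

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel: %s on %d complexes (scheme %s)\n", object@kind,
              length(object@trainingIds), object@scheme))
})

#' @describeIn FittedModel the descriptor scheme the model consumes
#' @param x,object a \code{FittedModel}
#' @export
modelScheme <- function(x) x@scheme

#' @describeIn FittedModel ids of the training complexes
#' @export
modelTrainingIds <- function(x) x@trainingIds

.designMatrix <- function(X) {
  cbind(`(Intercept)` = 1, featureMatrix(X))
}

#' Fit multiple linear regression
#'
#' Ordinary least squares with intercept via the SVD pseudoinverse:
#' refitting on identical input is bit-identical, and rank-deficient
#' designs yield the minimum-norm coefficient vector (with a warning)
#' instead of failing.
#'
#' @param X a \linkS4class{DescriptorTable}.
#' @param y numeric affinities (pKd) aligned to the rows of \code{X};
#'   defaults to the table's own affinity column.
#' @return A \linkS4class{FittedModel} of kind \code{"MLR"}.
#' @export
fitMLR <- function(X, y = affinities(X)) {
  if (length(y) != length(complexIds(X)))
    stop("y must align with the rows of X")
  n <- length(y)
  if (n < 2) stop("need at least 2 training complexes")
  A <- .designMatrix(X)
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  if (sum(pos) < ncol(A))
    warning("rank-deficient design; returning the minimum-norm solution",
            call. = FALSE)
  coefs <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  coefs <- drop(coefs)
  names(coefs) <- colnames(A)
  new("FittedModel", kind = "MLR", fit = coefs, seed = NA_integer_,
      trainingIds = complexIds(X), scheme = descriptorScheme(X),
      featureNames = colnames(featureMatrix(X)))
}

#' Fit a random-forest scoring function
#'
#' Regression forest in the RF-Score tradition: \code{nTrees} trees, each
#' grown on a size-n bootstrap resample with \eqn{\lceil p/3 \rceil}
#' candidate features per split (by default) and unlimited depth;
#' prediction is the mean over trees. Identical (data, spec, seed) yields
#' an identical model (single-threaded ranger backend).
#'
#' @inheritParams fitMLR
#' @param spec a \linkS4class{ModelSpec} of kind \code{"RF"}.
#' @param seed integer seed for this forest.
#' @return A \linkS4class{FittedModel} of kind \code{"RF"}.
#' @export
fitRF <- function(X, y = affinities(X), spec = modelSpec("RF"),
                  seed = spec@baseSeed) {
  if (length(y) != length(complexIds(X)))
    stop("y must align with the rows of X")
  if (length(y) < 2) stop("need at least 2 training complexes")
  feat <- featureMatrix(X)
  df <- data.frame(.y = y, feat, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = spec@nTrees, mtry = resolveMtry(spec, ncol(feat)),
    min.node.size = 5, replace = TRUE, sample.fraction = 1,
    seed = as.integer(seed), num.threads = 1, verbose = FALSE)
  new("FittedModel", kind = "RF", fit = fit, seed = as.integer(seed),
      trainingIds = complexIds(X), scheme = descriptorScheme(X),
      featureNames = colnames(feat))
}

#' Predict affinities for a descriptor table
#'
#' @param model a \linkS4class{FittedModel}.
#' @param X a \linkS4class{DescriptorTable} under the model's scheme.
#' @return Numeric vector of predicted affinities (pKd), one per row.
#' @export
predictAffinity <- function(model, X) {
  if (descriptorScheme(X) != model@scheme)
    stop(sprintf("scheme mismatch: model expects %s, table is %s",
                 model@scheme, descriptorScheme(X)))
  feat <- featureMatrix(X)[, model@featureNames, drop = FALSE]
  if (model@kind == "MLR") {
    drop(cbind(1, feat) %*% model@fit)
  } else {
    df <- data.frame(feat, check.names = FALSE)
    as.numeric(predict(model@fit, data = df, num.threads = 1)$predictions)
  }
}

#' Repeated fit/predict protocol
#'
#' Runs the repeat protocol used for stochastic scoring functions: repeat
#' \eqn{r} (0-based) is trained with seed \code{baseSeed + r} and asked to
#' predict the fixed test set. MLR is deterministic, so it is fitted once
#' and its prediction vector replicated.
#'
#' @param XTrain,XTest \linkS4class{DescriptorTable}s under one scheme.
#' @param yTrain training affinities (defaults to \code{XTrain}'s column).
#' @param spec a \linkS4class{ModelSpec}.
#' @return List of \code{nRepeats} prediction vectors.
#' @export
repeatFitPredict <- function(XTrain, XTest, yTrain = affinities(XTrain),
                             spec = modelSpec("RF")) {
  if (descriptorScheme(XTrain) != descriptorScheme(XTest))
    stop("train and test tables must share a scheme")
  if (spec@kind == "MLR") {
    pred <- predictAffinity(fitMLR(XTrain, yTrain), XTest)
    return(rep(list(pred), spec@nRepeats))
  }
  lapply(seq_len(spec@nRepeats) - 1L, function(r) {
    m <- fitRF(XTrain, yTrain, spec, seed = spec@baseSeed + r)
    predictAffinity(m, XTest)
  })
}
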