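# Scoring-power evaluation: test-set Pearson correlation, repeat
# summaries, the learning-curve table over (scoring function x cutoff),
# and the stability arithmetic (range, gap ratio).

#' Pearson correlation between predicted and measured affinities
#'
#' The scoring-power metric: sample Pearson product-moment correlation.
#' Degenerate inputs (constant vectors) raise an error rather than
#' returning a silent zero.
#'
#' @param yTrue measured affinities (pKd).
#' @param yPred predicted affinities.
#' @return Correlation in [-1, 1].
#' @export
pearsonRp <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  if (length(yTrue) < 3) stop("need at least 3 observations")
  if (stats::sd(yTrue) == 0 || stats::sd(yPred) == 0)
    stop("correlation undefined: constant input vector")
  stats::cor(yTrue, yPred)
}

#' Per-(scoring function, cutoff) repeat summary
#'
#' @slot sfName scoring-function name.
#' @slot cutoff similarity cutoff of the training set.
#' @slot nTrain training-set size.
#' @slot rpValues test-set Rp per repeat (may be NA for untrainable rows).
#' @slot meanRp,medianRp,minRp,maxRp,rangeRp summary statistics;
#'   \code{rangeRp = maxRp - minRp}.
#'
#' @exportClass RepeatSummary
setClass("RepeatSummary",
  representation(sfName = "character", cutoff = "numeric",
                 nTrain = "integer", rpValues = "numeric",
                 meanRp = "numeric", medianRp = "numeric",
                 minRp = "numeric", maxRp = "numeric", rangeRp = "numeric"))

setValidity("RepeatSummary", function(object) {
  rp <- object@rpValues[!is.na(object@rpValues)]
  msgs <- character(0)
  if (length(rp) && (any(rp < -1) || any(rp > 1)))
    msgs <- c(msgs, "Rp values must lie in [-1, 1]")
  if (length(rp) && object@rangeRp < 0)
    msgs <- c(msgs, "rangeRp must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Summarise Rp values of a repeat protocol
#'
#' Builds a \linkS4class{RepeatSummary} directly from per-repeat Rp
#' values (e.g. printed values from an external run).
#'
#' @param sfName scoring-function label.
#' @param cutoff training-set cutoff.
#' @param nTrain training-set size.
#' @param rpValues numeric Rp values, one per repeat.
#' @return A \linkS4class{RepeatSummary}.
#' @export
repeatSummaryFromRp <- function(sfName, cutoff, nTrain, rpValues) {
  rp <- as.numeric(rpValues)
  ok <- rp[!is.na(rp)]
  if (!length(ok))
    return(new("RepeatSummary", sfName = sfName, cutoff = as.numeric(cutoff),
               nTrain = as.integer(nTrain), rpValues = rp,
               meanRp = NA_real_, medianRp = NA_real_, minRp = NA_real_,
               maxRp = NA_real_, rangeRp = NA_real_))
  new("RepeatSummary", sfName = sfName, cutoff = as.numeric(cutoff),
      nTrain = as.integer(nTrain), rpValues = rp,
      meanRp = mean(ok), medianRp = stats::median(ok), minRp = min(ok),
      maxRp = max(ok), rangeRp = max(ok) - min(ok))
}

#' Summarise repeated predictions against measured affinities
#'
#' @param sfName scoring-function label.
#' @param cutoff training-set cutoff.
#' @param nTrain training-set size.
#' @param predictions list of prediction vectors (one per repeat).
#' @param yTrue measured test affinities.
#' @return A \linkS4class{RepeatSummary}.
#' @export
summarizeRepeats <- function(sfName, cutoff, nTrain, predictions, yTrue) {
  if (!length(predictions)) stop("empty prediction list")
  rp <- vapply(predictions, function(p) pearsonRp(yTrue, p), numeric(1))
  repeatSummaryFromRp(sfName, cutoff, nTrain, rp)
}

#' @describeIn summarizeRepeats one-row data.frame view of a summary
#' @param x a \code{RepeatSummary}
#' @export
repeatSummaryRow <- function(x) {
  data.frame(sf = x@sfName, cutoff = x@cutoff, n_train = x@nTrain,
             mean_rp = x@meanRp, median_rp = x@medianRp, min_rp = x@minRp,
             max_rp = x@maxRp, range_rp = x@rangeRp)
}

setMethod("show", "RepeatSummary", function(object) {
  cat(sprintf(
    "RepeatSummary %s @ cutoff %.3g (n=%d): mean %.3f median %.3f range %.3f\n",
    object@sfName, object@cutoff, object@nTrain, object@meanRp,
    object@medianRp, object@rangeRp))
})

#' Gap-to-variability ratio
#'
#' Expresses the performance gap between a stochastic scoring function
#' (median Rp, stochastic range) and a deterministic comparator as a
#' multiple of the stochastic variability range:
#' \code{(medianRpA - rpB) / rangeA}.
#'
#' @param medianRpA median Rp of the stochastic scoring function.
#' @param rpB Rp of the deterministic comparator.
#' @param rangeA max - min Rp over the stochastic repeats; must be > 0.
#' @return The ratio.
#' @export
gapRatio <- function(medianRpA, rpB, rangeA) {
  if (!is.numeric(rangeA) || rangeA <= 0)
    stop("rangeA must be positive (a deterministic comparator has no stochastic scale)")
  (medianRpA - rpB) / rangeA
}

#' Learning-curve table
#'
#' One row per (scoring function, cutoff) with the training-set size and
#' repeat summary; the long form carries every per-repeat Rp.
#'
#' @slot summary data.frame \code{sf, cutoff, n_train, mean_rp, median_rp,
#'   min_rp, max_rp, range_rp}.
#' @slot long data.frame \code{sf, cutoff, n_train, repeat, rp}.
#'
#' @exportClass LearningCurve
setClass("LearningCurve",
  representation(summary = "data.frame", long = "data.frame"))

#' @describeIn LearningCurve summary table accessor
#' @param x,object a \code{LearningCurve}
#' @export
curveSummary <- function(x) x@summary

#' @describeIn LearningCurve long-form (per-repeat) table accessor
#' @export
curveLong <- function(x) x@long

setMethod("show", "LearningCurve", function(object) {
  cat(sprintf("LearningCurve: %d scoring function(s) x %d cutoff(s)\n",
              length(unique(object@summary$sf)),
              length(unique(object@summary$cutoff))))
})

#' Build the learning-curve table
#'
#' For every scoring function in the roster and every cutoff of the
#' partition: train on the retained training complexes only, predict the
#' fixed test set (identical across all rows), and summarise the repeat
#' Rp values. Cutoffs retaining fewer than two complexes are reported with
#' NA Rp (flagged untrainable) rather than dropped.
#'
#' @param descriptorTables named list of \linkS4class{DescriptorTable}s
#'   (one per scheme used in the roster) covering every train and test
#'   complex, each carrying affinities.
#' @param partition a \linkS4class{NestedPartition} over the training ids.
#' @param testIds ids of the fixed test set.
#' @param roster list of scoring-function configs, each a list with
#'   \code{name}, \code{scheme} and \code{spec} (a
#'   \linkS4class{ModelSpec}).
#' @return A \linkS4class{LearningCurve}.
#' @export
buildLearningCurve <- function(descriptorTables, partition, testIds, roster) {
  if (!length(roster)) stop("empty scoring-function roster")
  sumRows <- list()
  longRows <- list()
  for (cfg in roster) {
    tab <- descriptorTables[[cfg$scheme]]
    if (is.null(tab))
      stop("no descriptor table for scheme ", cfg$scheme)
    XTest <- subsetComplexes(tab, testIds)
    yTest <- affinities(XTest)
    for (co in cutoffSchedule(partition)) {
      ids <- retainedIds(partition, co)
      if (length(ids) < 2) {
        rs <- repeatSummaryFromRp(cfg$name, co, length(ids),
                                  rep(NA_real_, cfg$spec@nRepeats))
      } else {
        XTrain <- subsetComplexes(tab, ids)
        preds <- repeatFitPredict(XTrain, XTest, affinities(XTrain),
                                  cfg$spec)
        ## degenerate fits (e.g. constant predictions from a 2-complex
        ## training set) are flagged NA, not fatal
        rp <- vapply(preds, function(p)
          tryCatch(pearsonRp(yTest, p), error = function(e) NA_real_),
          numeric(1))
        rs <- repeatSummaryFromRp(cfg$name, co, length(ids), rp)
      }
      sumRows[[length(sumRows) + 1L]] <- repeatSummaryRow(rs)
      longRows[[length(longRows) + 1L]] <- data.frame(
        sf = cfg$name, cutoff = co, n_train = length(ids),
        repeat_index = seq_along(rs@rpValues), rp = rs@rpValues)
    }
  }
  new("LearningCurve", summary = do.call(rbind, sumRows),
      long = do.call(rbind, longRows))
}

#' Write learning-curve CSVs
#'
#' Emits the long form (\code{sf,cutoff,n_train,repeat,rp}) and the
#' summary form; Rp values are written to three decimals.
#'
#' @param curve a \linkS4class{LearningCurve}.
#' @param summaryPath,longPath output files (either may be NULL to skip).
#' @export
writeLearningCurveCSV <- function(curve, summaryPath = NULL,
                                  longPath = NULL) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
  if (!is.null(summaryPath)) {
    s <- curveSummary(curve)
    out <- data.frame(sf = s$sf, cutoff = s$cutoff, n_train = s$n_train,
                      mean_rp = fmt(s$mean_rp), median_rp = fmt(s$median_rp),
                      min_rp = fmt(s$min_rp), max_rp = fmt(s$max_rp),
                      range_rp = fmt(s$range_rp))
    utils::write.csv(out, summaryPath, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(longPath)) {
    l <- curveLong(curve)
    out <- data.frame(sf = l$sf, cutoff = l$cutoff, n_train = l$n_train,
                      `repeat` = l$repeat_index, rp = fmt(l$rp),
                      check.names = FALSE)
    utils::write.csv(out, longPath, row.names = FALSE, quote = FALSE)
  }
  invisible(curve)
}

#' Plot a learning curve
#'
#' Mean test-set Rp against the number of training samples, one line per
#' scoring function (the horizontal axis is n_train, not the cutoff).
#' Requires ggplot2.
#'
#' @param curve a \linkS4class{LearningCurve}.
#' @return A ggplot object.
#' @export
plotLearningCurve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  s <- curveSummary(curve)
  s <- s[!is.na(s$mean_rp), ]
  ggplot2::ggplot(s, ggplot2::aes(x = n_train, y = mean_rp, colour = sf)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of training samples", y = "test-set Rp",
                  colour = "scoring function") +
    ggplot2::theme_minimal()
}
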