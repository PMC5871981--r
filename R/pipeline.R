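# End-to-end orchestration: synthetic mode (seed -> benchmark -> curves)
# and files mode (structure/affinity/similarity files -> curves), with a
# self-describing manifest and CSV outputs.

#' Default scoring-function roster
#'
#' Four scoring functions spanning the classical-vs-machine-learning
#' comparison: a deterministic MLR on the four X-Score-like terms
#' (\code{X-Score}), its random-forest variant on the identical features
#' (\code{RF::X-Score}), the 36-count random forest (\code{RF-Score}) and
#' the 42-feature random forest (\code{RF-Score-v3}).
#'
#' @param nRepeats training repeats per cutoff for the stochastic models.
#' @param nTrees trees per forest.
#' @param baseSeed base seed for the repeat protocol.
#' @return List of roster entries (\code{name}, \code{scheme},
#'   \code{spec}).
#' @export
defaultRoster <- function(nRepeats = 10L, nTrees = 500L, baseSeed = 1L) {
  list(
    list(name = "X-Score", scheme = "xscore4",
         spec = modelSpec("MLR", nRepeats = nRepeats, baseSeed = baseSeed)),
    list(name = "RF::X-Score", scheme = "xscore4",
         spec = modelSpec("RF", nTrees = nTrees, nRepeats = nRepeats,
                          baseSeed = baseSeed)),
    list(name = "RF-Score", scheme = "rf_v1",
         spec = modelSpec("RF", nTrees = nTrees, nRepeats = nRepeats,
                          baseSeed = baseSeed)),
    list(name = "RF-Score-v3", scheme = "rf_v3",
         spec = modelSpec("RF", nTrees = nTrees, nRepeats = nRepeats,
                          baseSeed = baseSeed)))
}

#' Run configuration
#'
#' @param mode \code{"synthetic"} or \code{"files"}.
#' @param masterSeed master seed (synthetic mode).
#' @param synthConfig generator configuration (synthetic mode).
#' @param inputDir exported-benchmark directory (files mode).
#' @param cutoffs ascending cutoff schedule.
#' @param roster scoring-function roster (see
#'   \code{\link{defaultRoster}}).
#' @param outputDir directory for CSV/JSON outputs, or NULL to skip
#'   writing.
#' @return Configuration list for \code{\link{runPipeline}}.
#' @export
runConfig <- function(mode = c("synthetic", "files"), masterSeed = 1L,
                      synthConfig = benchmarkConfig(), inputDir = NULL,
                      cutoffs = defaultCutoffSchedule("structural"),
                      roster = defaultRoster(), outputDir = NULL) {
  mode <- match.arg(mode)
  validateCutoffSchedule(cutoffs)
  if (!length(roster)) stop("roster must be nonempty")
  if (mode == "files" && (is.null(inputDir) || !dir.exists(inputDir)))
    stop("files mode requires an existing inputDir")
  list(mode = mode, masterSeed = as.integer(masterSeed),
       synthConfig = synthConfig, inputDir = inputDir, cutoffs = cutoffs,
       roster = roster, outputDir = outputDir)
}

.descriptorTablesFromComplexes <- function(complexes, schemes, cutoff = 12) {
  ids <- names(complexes)
  out <- list()
  for (scheme in schemes) {
    rows <- lapply(complexes, function(cr)
      computeDescriptors(cr$protein, cr$ligand, scheme, cutoff))
    out[[scheme]] <- DescriptorTable(
      ids, do.call(rbind, rows), scheme,
      vapply(complexes, function(cr) cr$affinity, numeric(1)))
  }
  out
}

#' Run the full benchmark pipeline
#'
#' Loads or generates the complexes, computes descriptors for every
#' scheme in the roster, builds the nested training sets, runs the
#' repeated training protocol for every (scoring function, cutoff), and
#' (optionally) writes the learning-curve CSVs, the partition report, a
#' stability report at the largest cutoff, and a manifest.
#'
#' @param config list from \code{\link{runConfig}}.
#' @param verbose print stage progress.
#' @return List with \code{curve} (\linkS4class{LearningCurve}),
#'   \code{partition}, \code{report} (partition report data.frame),
#'   \code{stability} (per stochastic scoring function: range and
#'   gap-to-variability ratio against the first MLR entry at the largest
#'   cutoff) and \code{manifest}.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  schemes <- unique(vapply(config$roster, `[[`, character(1), "scheme"))

  if (config$mode == "synthetic") {
    say("generating synthetic benchmark (seed %d)", config$masterSeed)
    bench <- makeBenchmark(config$synthConfig, config$masterSeed)
    say("computing descriptors for %d complexes under %d scheme(s)",
        length(bench@complexes), length(schemes))
    tables <- lapply(schemes, function(s) benchmarkDescriptors(bench, s))
    names(tables) <- schemes
    sim <- benchmarkSimilarity(bench)
    teIds <- benchmarkTestIds(bench)
  } else {
    say("loading benchmark from %s", config$inputDir)
    input <- importBenchmark(config$inputDir)
    say("computing descriptors for %d complexes under %d scheme(s)",
        length(input$complexes), length(schemes))
    tables <- .descriptorTablesFromComplexes(input$complexes, schemes)
    sim <- input$similarity
    teIds <- input$testIds
  }

  part <- buildNestedSets(sim, config$cutoffs)
  report <- partitionReport(part)
  say("partition: %s",
      paste(report$n_train, collapse = " "))

  curve <- buildLearningCurve(tables, part, teIds, config$roster)
  say("learning curve complete (%d rows)", nrow(curveSummary(curve)))

  ## stability at the largest cutoff: stochastic range and, when an MLR
  ## comparator is present, the gap-to-variability ratio
  s <- curveSummary(curve)
  topCut <- max(config$cutoffs)
  top <- s[s$cutoff == topCut, ]
  mlrNames <- vapply(Filter(function(cf) cf$spec@kind == "MLR",
                            config$roster), `[[`, character(1), "name")
  stability <- NULL
  if (nrow(top)) {
    stability <- top[, c("sf", "n_train", "median_rp", "range_rp")]
    stability$gap_ratio <- NA_real_
    if (length(mlrNames) && mlrNames[1] %in% top$sf) {
      rpB <- top$median_rp[top$sf == mlrNames[1]][1]
      for (i in seq_len(nrow(stability))) {
        if (!stability$sf[i] %in% mlrNames &&
            !is.na(stability$range_rp[i]) && stability$range_rp[i] > 0)
          stability$gap_ratio[i] <-
            gapRatio(stability$median_rp[i], rpB, stability$range_rp[i])
      }
    }
  }

  manifest <- list(
    mode = config$mode, master_seed = config$masterSeed,
    cutoffs = config$cutoffs,
    roster = lapply(config$roster, function(cf)
      list(name = cf$name, scheme = cf$scheme, kind = cf$spec@kind,
           n_trees = cf$spec@nTrees, n_repeats = cf$spec@nRepeats,
           base_seed = cf$spec@baseSeed)),
    n_train = length(fullTrainingIds(part)), n_test = length(teIds),
    complete = TRUE)

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    writeLearningCurveCSV(curve,
                          file.path(config$outputDir, "curve_summary.csv"),
                          file.path(config$outputDir, "curve_long.csv"))
    utils::write.csv(report, file.path(config$outputDir, "partition.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(stability))
      utils::write.csv(stability,
                       file.path(config$outputDir, "stability.csv"),
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(curve = curve, partition = part, report = report,
       stability = stability, manifest = manifest)
}
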