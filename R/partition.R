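# Similarity-cutoff nested training sets: the benchmark design where a
# training complex is dropped once any single test complex is more similar
# than the cutoff, yielding training sets nested by construction.

#' Train-by-test protein similarity matrix
#'
#' @slot values numeric matrix in [0, 1]; rownames are training-complex
#'   ids, colnames test-complex ids.
#'
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("matrix must have train ids as rownames and test ids as colnames")
  if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
    msgs <- c(msgs, "train and test ids must be unique")
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    msgs <- c(msgs, "similarity values must be finite and in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values numeric matrix of similarities in [0, 1] with train ids
#'   as rownames and test ids as colnames.
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
SimilarityMatrix <- function(values) {
  new("SimilarityMatrix", values = as.matrix(values))
}

#' @describeIn SimilarityMatrix training-complex ids
#' @param x,object a \code{SimilarityMatrix}
#' @export
trainIds <- function(x) rownames(x@values)

#' @describeIn SimilarityMatrix test-complex ids
#' @export
testIds <- function(x) colnames(x@values)

#' @describeIn SimilarityMatrix raw value matrix
#' @export
similarityValues <- function(x) x@values

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d train x %d test, values in [%.3f, %.3f]\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

#' Nested training-set partition
#'
#' For cutoffs \eqn{c_1 < c_2}, \code{retained(c1)} is a subset of
#' \code{retained(c2)} by construction (the retain rule is monotone in the
#' cutoff).
#'
#' @slot cutoffs ascending numeric cutoffs.
#' @slot retained list of character vectors of retained train ids, one per
#'   cutoff.
#' @slot fullIds the complete training-id set.
#'
#' @exportClass NestedPartition
setClass("NestedPartition",
  representation(cutoffs = "numeric", retained = "list",
                 fullIds = "character"))

setValidity("NestedPartition", function(object) {
  msgs <- character(0)
  if (length(object@cutoffs) != length(object@retained))
    msgs <- c(msgs, "one retained set per cutoff required")
  if (is.unsorted(object@cutoffs, strictly = TRUE))
    msgs <- c(msgs, "cutoffs must be strictly ascending")
  k <- length(object@retained)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      if (!all(object@retained[[i]] %in% object@retained[[i + 1]]))
        msgs <- c(msgs, sprintf("nesting violated between cutoffs %g and %g",
                                object@cutoffs[i], object@cutoffs[i + 1]))
    }
  }
  if (!all(unlist(object@retained) %in% object@fullIds))
    msgs <- c(msgs, "retained ids must come from the full training set")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn NestedPartition the cutoff schedule
#' @param x,object a \code{NestedPartition}
#' @export
cutoffSchedule <- function(x) x@cutoffs

#' @describeIn NestedPartition retained training ids at one cutoff
#' @param cutoff one cutoff value present in the schedule
#' @export
retainedIds <- function(x, cutoff) {
  i <- match(cutoff, x@cutoffs)
  if (is.na(i)) stop("cutoff ", cutoff, " not in the schedule")
  x@retained[[i]]
}

#' @describeIn NestedPartition the full training-id set
#' @export
fullTrainingIds <- function(x) x@fullIds

setMethod("show", "NestedPartition", function(object) {
  cat(sprintf("NestedPartition: %d cutoffs over %d training complexes\n",
              length(object@cutoffs), length(object@fullIds)))
  sizes <- vapply(object@retained, length, integer(1))
  cat(paste(sprintf("  %.3g -> %d", object@cutoffs, sizes), collapse = "\n"),
      "\n")
})

#' Validate a cutoff schedule
#'
#' @param cutoffs numeric vector; must be nonempty, strictly ascending and
#'   within (0, 1].
#' @return The schedule, invisibly, after validation.
#' @export
validateCutoffSchedule <- function(cutoffs) {
  if (!length(cutoffs) || !is.numeric(cutoffs))
    stop("cutoff schedule must be a nonempty numeric vector")
  if (any(cutoffs <= 0) || any(cutoffs > 1))
    stop("cutoffs must lie in (0, 1]")
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly ascending")
  invisible(cutoffs)
}

#' Default cutoff schedules
#'
#' The 13-point structural-like schedule (0.30 to 0.85 in steps of 0.05,
#' closing at 1.0) and the 11-point sequence-like schedule (0.20 to 0.875
#' in steps of 0.075, closing at 1.0). The final cutoff of 1.0 retains
#' the full training set, the benchmark's largest nested set. Only the
#' schedule shapes are standardized; any ascending schedule in (0, 1] is
#' accepted by the partition functions.
#'
#' @param kind \code{"structural"} (13 points) or \code{"sequence"} (11
#'   points).
#' @return Numeric cutoff schedule.
#' @export
defaultCutoffSchedule <- function(kind = c("structural", "sequence")) {
  kind <- match.arg(kind)
  if (kind == "structural") c(seq(0.30, 0.85, by = 0.05), 1.0)
  else c(round(seq(0.20, 0.875, by = 0.075), 3), 1.0)
}

#' Maximum similarity of a training complex to any test complex
#'
#' @param S a \linkS4class{SimilarityMatrix}.
#' @param trainId one training-complex id.
#' @return The maximum over test columns of the complex's similarity row.
#' @export
maxTestSimilarity <- function(S, trainId) {
  v <- similarityValues(S)
  if (!trainId %in% rownames(v)) stop("unknown training id: ", trainId)
  max(v[trainId, ])
}

#' Build nested training sets from a similarity matrix
#'
#' For each cutoff \eqn{c}, retains the training complexes whose maximum
#' similarity to any test complex is at most \eqn{c}: a training complex
#' is excluded as soon as a single test complex is more similar than the
#' cutoff, and ties at the cutoff are retained (closed boundary).
#'
#' @param S a \linkS4class{SimilarityMatrix}.
#' @param cutoffs ascending cutoff schedule in (0, 1].
#' @return A \linkS4class{NestedPartition}.
#' @export
buildNestedSets <- function(S, cutoffs) {
  validateCutoffSchedule(cutoffs)
  v <- similarityValues(S)
  rowMax <- apply(v, 1, max)
  retained <- lapply(cutoffs, function(co) rownames(v)[rowMax <= co])
  new("NestedPartition", cutoffs = as.numeric(cutoffs), retained = retained,
      fullIds = rownames(v))
}

#' Partition size report
#'
#' @param P a \linkS4class{NestedPartition}.
#' @param totalN total number of training complexes (denominator of the
#'   percentage column).
#' @return data.frame with columns \code{cutoff}, \code{n_train} and
#'   \code{percent} (to one decimal).
#' @export
partitionReport <- function(P, totalN = length(fullTrainingIds(P))) {
  if (!is.numeric(totalN) || totalN <= 0)
    stop("totalN must be a positive count")
  sizes <- vapply(P@retained, length, integer(1))
  if (totalN < max(sizes)) stop("totalN smaller than a retained set")
  data.frame(cutoff = P@cutoffs, n_train = sizes,
             percent = round(100 * sizes / totalN, 1))
}

#' Percent of training data retained
#'
#' Convenience for the arithmetic used in partition reports:
#' \code{100 * nRetained / totalN} rounded to one decimal.
#'
#' @param nRetained retained-set size.
#' @param totalN full training-set size.
#' @return Percentage to one decimal.
#' @export
percentOfTraining <- function(nRetained, totalN) {
  if (!is.numeric(totalN) || totalN <= 0)
    stop("totalN must be a positive count")
  round(100 * nRetained / totalN, 1)
}

#' Similarity matrix CSV round trip
#'
#' Dialect: header row of test ids with an empty leading cell, one row per
#' training complex, first column the training id.
#'
#' @param S a \linkS4class{SimilarityMatrix}.
#' @param path file path.
#' @export
writeSimilarityCSV <- function(S, path) {
  v <- similarityValues(S)
  header <- paste(c("id", colnames(v)), collapse = ",")
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], formatC(v[i, ], format = "g", digits = 17)),
          collapse = ","), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname writeSimilarityCSV
#' @return \code{readSimilarityCSV} returns the parsed
#'   \linkS4class{SimilarityMatrix}.
#' @export
readSimilarityCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  SimilarityMatrix(m)
}
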