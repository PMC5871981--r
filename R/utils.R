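# Shared constants and small helpers.

## Element vocabulary for the atom-pair count descriptors: nine ligand
## elements crossed with four protein elements gives the 36 ordered
## (ligand, protein) pairs, ligand-major.
.LIGAND_ELEMENTS <- c("C", "N", "O", "F", "P", "S", "CL", "BR", "I")
.PROTEIN_ELEMENTS <- c("C", "N", "O", "S")

## van der Waals radii (Angstrom) used for surface distances in the
## empirical terms; unknown elements fall back to the generic radius.
.VDW_RADII <- c(
  C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1,
  F = 1.5, CL = 1.8, BR = 2.0, I = 2.2
)
.VDW_DEFAULT <- 1.8

vdwRadius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  miss <- is.na(r)
  if (any(miss)) {
    warning("unknown element(s) ", paste(unique(element[miss]), collapse = ", "),
            "; using generic vdW radius ", .VDW_DEFAULT, " Angstrom",
            call. = FALSE)
    r[miss] <- .VDW_DEFAULT
  }
  unname(r)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Derive a reproducible integer seed for a named substream of a master
## seed. Streams are fixed at call sites so components can be regenerated
## independently; arithmetic stays below 2^31.
substreamSeed <- function(masterSeed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(masterSeed) * 7919 + h * 104729) %% 2147483647)
}

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed, evaluates \code{expr}, and restores the caller's RNG
#' state, so seeded draws never perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## All-pairs Euclidean distance between two coordinate matrices (n x 3,
## m x 3) -> n x m matrix.
crossDistances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
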