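#' @import methods
NULL

#' Heavy-atom molecular structure
#'
#' Minimal structural model consumed by the descriptor schemes: an ordered
#' table of heavy atoms (element, coordinates in Angstrom, ordinal in the
#' source file) plus, for ligands, a bond list. Hydrogens are stripped on
#' read and never appear in a valid object.
#'
#' @slot atoms data.frame with columns \code{element} (uppercase symbol),
#'   \code{x}, \code{y}, \code{z} (Angstrom) and \code{source_index}.
#' @slot role either \code{"protein"} or \code{"ligand"}.
#' @slot bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices) and \code{order} (1, 2, 3, or 4 for aromatic); empty for
#'   proteins.
#'
#' @exportClass MolecularStructure
setClass("MolecularStructure",
  representation(atoms = "data.frame", role = "character",
                 bonds = "data.frame"))

setValidity("MolecularStructure", function(object) {
  a <- object@atoms
  msgs <- character(0)
  need <- c("element", "x", "y", "z", "source_index")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (!all(grepl("^[A-Za-z]+$", a$element)))
    msgs <- c(msgs, "elements must be nonempty alphabetic tokens")
  if (any(toupper(a$element) %in% c("H", "D")))
    msgs <- c(msgs, "hydrogen atoms are not allowed")
  if (!all(is.finite(c(a$x, a$y, a$z))))
    msgs <- c(msgs, "coordinates must be finite")
  if (!(length(object@role) == 1L && object@role %in% c("protein", "ligand")))
    msgs <- c(msgs, "role must be 'protein' or 'ligand'")
  b <- object@bonds
  if (nrow(b)) {
    if (!all(c("i", "j", "order") %in% names(b)))
      msgs <- c(msgs, "bonds must have columns i, j, order")
    else {
      if (any(b$i < 1 | b$i > nrow(a) | b$j < 1 | b$j > nrow(a)))
        msgs <- c(msgs, "bond indices out of range")
      if (any(b$i == b$j)) msgs <- c(msgs, "self-bonds are not allowed")
      if (!all(b$order %in% c(1L, 2L, 3L, 4L)))
        msgs <- c(msgs, "bond order must be 1, 2, 3 or 4 (aromatic)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

emptyBonds <- function() {
  data.frame(i = integer(0), j = integer(0), order = integer(0))
}

#' Construct a MolecularStructure
#'
#' @param elements character vector of uppercase element symbols.
#' @param coords numeric matrix (n x 3) of coordinates in Angstrom.
#' @param role \code{"protein"} or \code{"ligand"}.
#' @param bonds optional data.frame (\code{i}, \code{j}, \code{order}).
#' @param sourceIndex ordinal of each atom in its source file.
#' @return A \linkS4class{MolecularStructure}.
#' @export
MolecularStructure <- function(elements, coords, role,
                               bonds = emptyBonds(),
                               sourceIndex = seq_along(elements)) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  atoms <- data.frame(element = toupper(as.character(elements)),
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      source_index = as.integer(sourceIndex))
  new("MolecularStructure", atoms = atoms, role = role,
      bonds = as.data.frame(bonds))
}

#' @describeIn MolecularStructure number of heavy atoms
#' @param x,object a \code{MolecularStructure}
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' @describeIn MolecularStructure atom table accessor
#' @export
atomTable <- function(x) x@atoms

#' @describeIn MolecularStructure bond table accessor
#' @export
bondTable <- function(x) x@bonds

#' @describeIn MolecularStructure element symbols
#' @export
elements <- function(x) x@atoms$element

#' @describeIn MolecularStructure coordinate matrix (n x 3, Angstrom)
#' @export
coordMatrix <- function(x) {
  as.matrix(x@atoms[, c("x", "y", "z"), drop = FALSE])
}

#' @describeIn MolecularStructure structure role ("protein"/"ligand")
#' @export
structureRole <- function(x) x@role

setMethod("show", "MolecularStructure", function(object) {
  cat(sprintf("MolecularStructure (%s): %d heavy atoms, %d bonds\n",
              object@role, nrow(object@atoms), nrow(object@bonds)))
  tab <- sort(table(object@atoms$element), decreasing = TRUE)
  cat("  elements:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
})

#' Descriptor table
#'
#' A set of per-complex descriptor vectors under one scheme, keyed by
#' complex id, optionally carrying measured affinities (pKd units).
#'
#' @slot ids character vector of unique complex ids.
#' @slot features numeric matrix (complexes x features) with feature names
#'   as column names.
#' @slot scheme one of \code{"rf_v1"}, \code{"vina6"}, \code{"rf_v3"},
#'   \code{"xscore4"}, \code{"external"}.
#' @slot affinity numeric vector of affinities aligned to \code{ids}, or
#'   length zero when absent.
#'
#' @exportClass DescriptorTable
setClass("DescriptorTable",
  representation(ids = "character", features = "matrix",
                 scheme = "character", affinity = "numeric"))

.SCHEME_SIZES <- c(rf_v1 = 36L, vina6 = 6L, rf_v3 = 42L, xscore4 = 4L)

setValidity("DescriptorTable", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, paste("duplicate id:",
                          object@ids[duplicated(object@ids)][1]))
  if (length(object@ids) != nrow(object@features))
    msgs <- c(msgs, "ids and feature rows differ in length")
  if (!length(object@scheme) == 1L ||
      !object@scheme %in% c(names(.SCHEME_SIZES), "external"))
    msgs <- c(msgs, "unknown scheme")
  else if (object@scheme %in% names(.SCHEME_SIZES) &&
           ncol(object@features) != .SCHEME_SIZES[[object@scheme]])
    msgs <- c(msgs, sprintf("scheme %s requires %d features, got %d",
                            object@scheme, .SCHEME_SIZES[[object@scheme]],
                            ncol(object@features)))
  if (anyNA(object@features) || any(!is.finite(object@features)))
    msgs <- c(msgs, "missing or non-finite feature values")
  if (length(object@affinity) &&
      length(object@affinity) != length(object@ids))
    msgs <- c(msgs, "affinity length must match ids")
  if (is.null(colnames(object@features)))
    msgs <- c(msgs, "features must have column names")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DescriptorTable
#'
#' @param ids complex ids (unique).
#' @param features numeric matrix, rows aligned to \code{ids}.
#' @param scheme descriptor scheme label.
#' @param affinity optional affinities (pKd).
#' @return A \linkS4class{DescriptorTable}.
#' @export
DescriptorTable <- function(ids, features, scheme,
                            affinity = numeric(0)) {
  new("DescriptorTable", ids = as.character(ids),
      features = as.matrix(features), scheme = scheme,
      affinity = as.numeric(affinity))
}

#' @describeIn DescriptorTable complex ids
#' @param x,object a \code{DescriptorTable}
#' @export
complexIds <- function(x) x@ids

#' @describeIn DescriptorTable feature matrix accessor
#' @export
featureMatrix <- function(x) x@features

#' @describeIn DescriptorTable descriptor scheme label
#' @export
descriptorScheme <- function(x) x@scheme

#' @describeIn DescriptorTable affinities (length 0 when absent)
#' @export
affinities <- function(x) x@affinity

#' @describeIn DescriptorTable subset by complex id
#' @param ids character vector of ids to keep, in order
#' @export
subsetComplexes <- function(x, ids) {
  idx <- match(ids, x@ids)
  if (anyNA(idx))
    stop("unknown complex id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  DescriptorTable(x@ids[idx], x@features[idx, , drop = FALSE], x@scheme,
                  if (length(x@affinity)) x@affinity[idx] else numeric(0))
}

setMethod("show", "DescriptorTable", function(object) {
  cat(sprintf("DescriptorTable: %d complexes x %d features (scheme %s)%s\n",
              length(object@ids), ncol(object@features), object@scheme,
              if (length(object@affinity)) ", with affinities" else ""))
})
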