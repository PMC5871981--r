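# Descriptor schemes: intermolecular atom-pair counts (36), Vina-style
# empirical terms (6), their concatenation (42), and a four-term
# X-Score-like surrogate. All schemes are heavy-atom based and rigid-motion
# invariant by construction (they depend only on interatomic distances and
# the ligand bond graph).

#' Names of the 36 atom-pair count features
#'
#' Ligand-major ordering over ligand elements
#' \{C, N, O, F, P, S, Cl, Br, I\} crossed with protein elements
#' \{C, N, O, S\}: \code{C.C, C.N, C.O, C.S, N.C, ...}.
#'
#' @return Character vector of length 36.
#' @export
pairCountFeatureNames <- function() {
  as.vector(t(outer(.LIGAND_ELEMENTS, .PROTEIN_ELEMENTS,
                    function(l, p) paste(l, p, sep = "."))))
}

#' Intermolecular atom-pair count descriptors
#'
#' For each ordered (ligand element, protein element) pair over the nine
#' ligand and four protein element types, counts the protein-ligand atom
#' pairs whose Euclidean distance is at most \code{cutoff} (closed
#' boundary). Atoms whose element lies outside the respective set
#' contribute nothing.
#'
#' @param protein,ligand \linkS4class{MolecularStructure} objects.
#' @param cutoff neighbour cutoff in Angstrom (default 12).
#' @return Named numeric vector of 36 nonnegative integer counts with
#'   attribute \code{scheme = "rf_v1"}.
#' @export
pairCounts <- function(protein, ligand, cutoff = 12) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive number (Angstrom)")
  if (!nAtoms(protein) || !nAtoms(ligand))
    stop("both structures must be nonempty")
  nm <- pairCountFeatureNames()
  counts <- setNames(numeric(36), nm)
  le <- elements(ligand)
  pe <- elements(protein)
  lkeep <- le %in% .LIGAND_ELEMENTS
  pkeep <- pe %in% .PROTEIN_ELEMENTS
  if (any(lkeep) && any(pkeep)) {
    d <- crossDistances(coordMatrix(ligand)[lkeep, , drop = FALSE],
                        coordMatrix(protein)[pkeep, , drop = FALSE])
    within <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(within)) {
      key <- paste(le[lkeep][within[, 1]], pe[pkeep][within[, 2]], sep = ".")
      tab <- table(key)
      counts[names(tab)] <- as.numeric(tab)
    }
  }
  structure(counts, scheme = "rf_v1")
}

## Piecewise empirical terms on the surface distance d = r - R_i - R_j,
## summed over heavy-atom pairs with center distance <= 8 Angstrom.
.vinaPairTerms <- function(d, ligElem, protElem) {
  gauss1 <- exp(-(d / 0.5)^2)
  gauss2 <- exp(-((d - 3) / 2)^2)
  repulsion <- ifelse(d < 0, d^2, 0)
  hydro <- ifelse(ligElem == "C" & protElem == "C",
                  clamp((1.5 - d) / 1.0, 0, 1), 0)
  polar <- ligElem %in% c("N", "O") & protElem %in% c("N", "O")
  hbond <- ifelse(polar, clamp(-d / 0.7, 0, 1), 0)
  cbind(gauss1 = gauss1, gauss2 = gauss2, repulsion = repulsion,
        hydrophobic = hydro, hbond = hbond)
}

#' Vina-style empirical terms
#'
#' Six descriptors in the spirit of AutoDock Vina's scoring terms: two
#' Gaussian attraction terms, a quadratic steric repulsion, a hydrophobic
#' ramp on carbon-carbon contacts and a hydrogen-bond ramp on N/O-N/O
#' contacts — each summed over protein-ligand heavy-atom pairs with center
#' distance at most 8 Angstrom, evaluated on the surface distance
#' \eqn{d = r - R_i - R_j} with tabulated van der Waals radii — plus the
#' ligand rotatable-bond count. The hydrophobic-atom definition is
#' simplified to element carbon.
#'
#' @inheritParams pairCounts
#' @return Named numeric vector \code{gauss1, gauss2, repulsion,
#'   hydrophobic, hbond, nrot} with attribute \code{scheme = "vina6"}.
#' @export
vinaTerms <- function(protein, ligand) {
  nrot <- countRotatableBonds(ligand)
  le <- elements(ligand)
  pe <- elements(protein)
  r <- crossDistances(coordMatrix(ligand), coordMatrix(protein))
  d <- r - outer(vdwRadius(le), vdwRadius(pe), "+")
  within <- which(r <= 8, arr.ind = TRUE)
  out <- c(gauss1 = 0, gauss2 = 0, repulsion = 0, hydrophobic = 0,
           hbond = 0, nrot = as.numeric(nrot))
  if (nrow(within)) {
    terms <- .vinaPairTerms(d[within], le[within[, 1]], pe[within[, 2]])
    out[1:5] <- colSums(terms)
  }
  structure(out, scheme = "vina6")
}

#' Full 42-feature descriptor vector
#'
#' Concatenation of the 36 atom-pair counts and the six Vina-style terms.
#'
#' @inheritParams pairCounts
#' @return Named numeric vector of length 42 with attribute
#'   \code{scheme = "rf_v3"}.
#' @export
rfV3Descriptors <- function(protein, ligand, cutoff = 12) {
  structure(c(pairCounts(protein, ligand, cutoff), vinaTerms(protein, ligand)),
            scheme = "rf_v3")
}

#' Four-term X-Score-like surrogate descriptors
#'
#' An explicitly approximate stand-in for the four energy terms of a
#' classical empirical scoring function: (1) a Lennard-Jones-like 8-4 van
#' der Waals sum \eqn{(d_0/r)^8 - 2 (d_0/r)^4} with \eqn{d_0 = R_i + R_j},
#' clamped per pair to \eqn{[-1, 10]}, over pairs within 8 Angstrom;
#' (2) a hydrogen-bond count of N/O-N/O pairs within 3.5 Angstrom; (3) a
#' hydrophobic-contact count of C-C pairs within 4.5 Angstrom; (4) the
#' ligand rotatable-bond count. These are not the published X-Score
#' energies — those require the original solvation/surface machinery — but
#' play the same structural role: a small, physically-motivated feature
#' set for linear regression.
#'
#' @inheritParams pairCounts
#' @return Named numeric vector \code{vdw, hbond, hydrophobic, rotor} with
#'   attribute \code{scheme = "xscore4"}.
#' @export
xscoreLikeTerms <- function(protein, ligand) {
  nrot <- countRotatableBonds(ligand)
  le <- elements(ligand)
  pe <- elements(protein)
  r <- crossDistances(coordMatrix(ligand), coordMatrix(protein))
  d0 <- outer(vdwRadius(le), vdwRadius(pe), "+")
  within <- which(r <= 8, arr.ind = TRUE)
  vdw <- 0
  hb <- 0
  hp <- 0
  if (nrow(within)) {
    rr <- r[within]
    ratio <- d0[within] / rr
    vdw <- sum(clamp(ratio^8 - 2 * ratio^4, -1, 10))
    polar <- le[within[, 1]] %in% c("N", "O") &
      pe[within[, 2]] %in% c("N", "O")
    hb <- sum(polar & rr <= 3.5)
    cc <- le[within[, 1]] == "C" & pe[within[, 2]] == "C"
    hp <- sum(cc & rr <= 4.5)
  }
  structure(c(vdw = vdw, hbond = hb, hydrophobic = hp,
              rotor = as.numeric(nrot)),
            scheme = "xscore4")
}

#' Compute a descriptor vector under a named scheme
#'
#' @inheritParams pairCounts
#' @param scheme one of \code{"rf_v1"}, \code{"vina6"}, \code{"rf_v3"},
#'   \code{"xscore4"}.
#' @return Named numeric vector for the requested scheme.
#' @export
computeDescriptors <- function(protein, ligand, scheme, cutoff = 12) {
  switch(scheme,
         rf_v1 = pairCounts(protein, ligand, cutoff),
         vina6 = vinaTerms(protein, ligand),
         rf_v3 = rfV3Descriptors(protein, ligand, cutoff),
         xscore4 = xscoreLikeTerms(protein, ligand),
         stop("unknown descriptor scheme: ", scheme))
}

#' Read a descriptor table from CSV
#'
#' Expects a header \code{id,<feature names...>[,affinity]}. Rejects
#' duplicate ids and missing or non-numeric cells.
#'
#' @param stream path to a CSV file or its content as character lines.
#' @param scheme scheme label to attach (\code{"external"} for foreign
#'   tables such as precomputed energy terms).
#' @return A \linkS4class{DescriptorTable}.
#' @export
loadDescriptorTable <- function(stream, scheme = "external") {
  lines <- .readLines(stream)
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        check.names = FALSE,
                        colClasses = "character")
  if (!"id" %in% names(df)) stop("descriptor CSV must have an 'id' column")
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop("duplicate id: ", dup[1])
  featCols <- setdiff(names(df), c("id", "affinity"))
  if (!length(featCols)) stop("descriptor CSV has no feature columns")
  feat <- matrix(NA_real_, nrow(df), length(featCols),
                 dimnames = list(NULL, featCols))
  for (jc in seq_along(featCols)) {
    v <- suppressWarnings(as.numeric(df[[featCols[jc]]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing value at row %d, column '%s'",
                   bad[1], featCols[jc]))
    feat[, jc] <- v
  }
  aff <- numeric(0)
  if ("affinity" %in% names(df)) {
    aff <- suppressWarnings(as.numeric(df$affinity))
    if (anyNA(aff)) stop("non-numeric affinity at row ", which(is.na(aff))[1])
  }
  DescriptorTable(df$id, feat, scheme, aff)
}

#' Write a descriptor table to CSV
#'
#' Counts are emitted as integers, real-valued terms with six significant
#' digits; decimal separator is always \code{"."}.
#'
#' @param x a \linkS4class{DescriptorTable}.
#' @param path output file.
#' @export
writeDescriptorTable <- function(x, path) {
  feat <- featureMatrix(x)
  fmt1 <- function(v) {
    ifelse(v == round(v) & abs(v) < 1e15, format(v, scientific = FALSE,
                                                 trim = TRUE),
           formatC(v, digits = 6, format = "g"))
  }
  cells <- apply(feat, 2, fmt1)
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(feat))
  header <- paste(c("id", colnames(feat),
                    if (length(affinities(x))) "affinity"), collapse = ",")
  rows <- apply(cbind(complexIds(x), cells,
                      if (length(affinities(x)))
                        formatC(affinities(x), digits = 6, format = "g")),
                1, paste, collapse = ",")
  writeLines(c(header, rows), path)
  invisible(path)
}
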