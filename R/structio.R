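# Structure readers: fixed-column PDB and V2000 SDF into the heavy-atom
# model, plus the canonical CSV dump and the rotatable-bond count.

.WATER_RESIDUES <- c("HOH", "WAT")

## Element inference when columns 77-78 are absent: take the leading
## alphabetic characters of the atom-name field; two-letter halogens are
## recognized by exact match, everything else collapses to its first letter
## (so "CA" is carbon, "SD" sulfur, per PDB naming).
inferElementFromName <- function(atomName) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[^A-Za-z]*", "", atomName)))
  vapply(nm, function(s) {
    if (!nzchar(s)) return("")
    if (s %in% c("CL", "BR")) return(s)
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

.readLines <- function(stream) {
  if (length(stream) == 1L && !grepl("\n", stream) && file.exists(stream))
    readLines(stream, warn = FALSE)
  else
    strsplit(paste(stream, collapse = "\n"), "\n", fixed = TRUE)[[1]]
}

#' Read a protein structure from PDB text
#'
#' Parses fixed-column ATOM (and, optionally, non-water HETATM) records of
#' the first model into a heavy-atom \linkS4class{MolecularStructure}.
#' Hydrogens/deuteriums and waters are excluded; alternate locations other
#' than blank or \code{"A"} are skipped. The element is taken from columns
#' 77-78 when present, otherwise inferred from the atom-name field.
#'
#' @param stream path to a PDB file, or the file content as a character
#'   vector of lines (or one string with embedded newlines).
#' @param includeCofactors logical; include non-water HETATM records
#'   (default \code{FALSE}).
#' @return A \linkS4class{MolecularStructure} with role \code{"protein"}.
#' @export
readProteinPDB <- function(stream, includeCofactors = FALSE) {
  lines <- .readLines(stream)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- substr(lines, 1, 6)
  keepType <- rec == "ATOM  " |
    (includeCofactors & rec == "HETATM")
  idx <- which(keepType)
  if (!length(idx))
    stop("no heavy atoms found after filtering (empty structure)")
  ln <- lines[idx]
  altLoc <- substr(ln, 17, 17)
  resName <- trimws(substr(ln, 18, 20))
  atomName <- substr(ln, 13, 16)
  elemCol <- trimws(substr(ln, 77, 78))
  element <- toupper(ifelse(nzchar(elemCol), elemCol,
                            inferElementFromName(atomName)))
  xs <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad))
    stop(sprintf("unparseable coordinates at line %d of the PDB input",
                 idx[bad[1]]))
  keep <- (altLoc %in% c(" ", "A")) &
    !(resName %in% .WATER_RESIDUES) &
    !(element %in% c("H", "D")) & nzchar(element)
  if (!any(keep))
    stop("no heavy atoms found after filtering (empty structure)")
  MolecularStructure(element[keep],
                     cbind(xs[keep], ys[keep], zs[keep]),
                     role = "protein",
                     sourceIndex = idx[keep])
}

#' Read a ligand from a V2000 SDF/MOL block
#'
#' Parses the counts line, atom block and bond block of a V2000 connection
#' table. Hydrogens are removed and bond indices re-mapped to the remaining
#' heavy atoms; bonds involving a removed hydrogen are dropped.
#'
#' @param stream path to an SDF/MOL file, or its content as character lines.
#' @return A \linkS4class{MolecularStructure} with role \code{"ligand"}.
#' @export
readLigandSDF <- function(stream) {
  lines <- .readLines(stream)
  if (length(lines) < 4L) stop("SDF input too short for a counts line")
  counts <- lines[4]
  nAtom <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nBond <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(nAtom) || is.na(nBond))
    stop("unparseable V2000 counts line: ", counts)
  if (length(lines) < 4L + nAtom + nBond)
    stop(sprintf(
      "counts line declares %d atoms and %d bonds but the file has only %d block lines",
      nAtom, nBond, length(lines) - 4L))
  atomLines <- lines[4L + seq_len(nAtom)]
  xs <- suppressWarnings(as.numeric(substr(atomLines, 1, 10)))
  ys <- suppressWarnings(as.numeric(substr(atomLines, 11, 20)))
  zs <- suppressWarnings(as.numeric(substr(atomLines, 21, 30)))
  elem <- toupper(trimws(substr(atomLines, 32, 34)))
  if (anyNA(xs) || anyNA(ys) || anyNA(zs))
    stop("unparseable coordinates in the SDF atom block (atom ",
         which(is.na(xs) | is.na(ys) | is.na(zs))[1], ")")
  bi <- bj <- border <- integer(0)
  if (nBond > 0) {
    bondLines <- lines[4L + nAtom + seq_len(nBond)]
    bi <- as.integer(substr(bondLines, 1, 3))
    bj <- as.integer(substr(bondLines, 4, 6))
    border <- as.integer(substr(bondLines, 7, 9))
    if (anyNA(bi) || anyNA(bj) || anyNA(border) ||
        any(bi < 1) || any(bi > nAtom) || any(bj < 1) || any(bj > nAtom))
      stop("invalid bond block entry in SDF input")
  }
  heavy <- !(elem %in% c("H", "D"))
  if (!any(heavy)) stop("no heavy atoms in SDF input (empty structure)")
  newIndex <- cumsum(heavy)
  keepBond <- heavy[bi] & heavy[bj]
  bonds <- data.frame(i = newIndex[bi][keepBond],
                      j = newIndex[bj][keepBond],
                      order = border[keepBond])
  MolecularStructure(elem[heavy], cbind(xs, ys, zs)[heavy, , drop = FALSE],
                     role = "ligand", bonds = bonds,
                     sourceIndex = which(heavy))
}

#' Count rotatable bonds
#'
#' A bond is counted as rotatable when it is a single (order-1) bond, does
#' not belong to any ring, and both endpoints have at least two heavy-atom
#' neighbours (i.e. neither end is terminal). Ring membership is decided on
#' the heavy-atom bond graph: a bond lies in a ring exactly when it is not
#' a bridge. No amide or conjugation perception is attempted; the count is
#' an approximation of torsion-tree sizing used by docking programs.
#'
#' @param mol a \linkS4class{MolecularStructure} with a bond list.
#' @return Nonnegative integer count.
#' @export
countRotatableBonds <- function(mol) {
  if (!is(mol, "MolecularStructure"))
    stop("mol must be a MolecularStructure")
  b <- bondTable(mol)
  if (is.null(b) || !all(c("i", "j", "order") %in% names(b)))
    stop("structure has no bond list")
  if (!nrow(b)) return(0L)
  g <- igraph::graph_from_edgelist(cbind(b$i, b$j), directed = FALSE)
  if (igraph::vcount(g) < nAtoms(mol))
    g <- igraph::add_vertices(g, nAtoms(mol) - igraph::vcount(g))
  deg <- igraph::degree(g)
  bridges <- igraph::bridges(g)
  inRing <- rep(TRUE, nrow(b))
  inRing[as.integer(bridges)] <- FALSE
  sum(b$order == 1L & !inRing & deg[b$i] >= 2 & deg[b$j] >= 2)
}

#' Canonical CSV dump of a structure
#'
#' Writes/reads the internal canonical form (\code{element,x,y,z} plus the
#' source index); re-reading a written structure reproduces its atoms
#' exactly. Bonds are serialized alongside for ligands.
#'
#' @param mol a \linkS4class{MolecularStructure}.
#' @param path output file.
#' @export
writeStructureCSV <- function(mol, path) {
  a <- atomTable(mol)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# role=%s", structureRole(mol)), con)
  writeLines("element,x,y,z,source_index", con)
  writeLines(sprintf("%s,%.6f,%.6f,%.6f,%d",
                     a$element, a$x, a$y, a$z, a$source_index), con)
  b <- bondTable(mol)
  if (nrow(b)) {
    writeLines("# bonds", con)
    writeLines(sprintf("%d,%d,%d", b$i, b$j, b$order), con)
  }
  invisible(path)
}

#' @rdname writeStructureCSV
#' @return \code{readStructureCSV} returns the parsed
#'   \linkS4class{MolecularStructure}.
#' @export
readStructureCSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  role <- sub("^# role=", "", lines[1])
  bondsAt <- which(lines == "# bonds")
  atomEnd <- if (length(bondsAt)) bondsAt - 1L else length(lines)
  atomLines <- lines[3:atomEnd]
  parts <- strsplit(atomLines, ",", fixed = TRUE)
  elem <- vapply(parts, `[`, character(1), 1)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  src <- vapply(parts, function(p) as.integer(p[5]), integer(1))
  bonds <- emptyBonds()
  if (length(bondsAt) && bondsAt < length(lines)) {
    bp <- strsplit(lines[(bondsAt + 1L):length(lines)], ",", fixed = TRUE)
    bonds <- data.frame(i = vapply(bp, function(p) as.integer(p[1]), integer(1)),
                        j = vapply(bp, function(p) as.integer(p[2]), integer(1)),
                        order = vapply(bp, function(p) as.integer(p[3]), integer(1)))
  }
  MolecularStructure(elem, xyz, role = role, bonds = bonds,
                     sourceIndex = src)
}
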