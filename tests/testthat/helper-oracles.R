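# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately written as plain scalar loops over the stated
# formulas, independent of the package's vectorised implementations.

LIG_ELEMS <- c("C", "N", "O", "F", "P", "S", "CL", "BR", "I")
PROT_ELEMS <- c("C", "N", "O", "S")
RADII <- c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1,
           F = 1.5, CL = 1.8, BR = 2.0, I = 2.2)
radiusOf <- function(e) if (e %in% names(RADII)) RADII[[e]] else 1.8

## brute-force pair counts: explicit double loop
bfPairCounts <- function(protein, ligand, cutoff = 12) {
  nm <- as.vector(t(outer(LIG_ELEMS, PROT_ELEMS, paste, sep = ".")))
  counts <- setNames(numeric(36), nm)
  pc <- coordMatrix(protein); pe <- elements(protein)
  lc <- coordMatrix(ligand); le <- elements(ligand)
  for (i in seq_len(nrow(lc))) {
    for (j in seq_len(nrow(pc))) {
      if (!(le[i] %in% LIG_ELEMS) || !(pe[j] %in% PROT_ELEMS)) next
      d <- sqrt(sum((lc[i, ] - pc[j, ])^2))
      if (d <= cutoff) {
        key <- paste(le[i], pe[j], sep = ".")
        counts[key] <- counts[key] + 1
      }
    }
  }
  counts
}

## brute-force Vina-style terms: per-pair scalar evaluation
bfVinaTerms <- function(protein, ligand) {
  pc <- coordMatrix(protein); pe <- elements(protein)
  lc <- coordMatrix(ligand); le <- elements(ligand)
  out <- c(gauss1 = 0, gauss2 = 0, repulsion = 0, hydrophobic = 0,
           hbond = 0, nrot = 0)
  for (i in seq_len(nrow(lc))) {
    for (j in seq_len(nrow(pc))) {
      r <- sqrt(sum((lc[i, ] - pc[j, ])^2))
      if (r > 8) next
      d <- r - radiusOf(le[i]) - radiusOf(pe[j])
      out["gauss1"] <- out["gauss1"] + exp(-(d / 0.5)^2)
      out["gauss2"] <- out["gauss2"] + exp(-((d - 3) / 2)^2)
      if (d < 0) out["repulsion"] <- out["repulsion"] + d^2
      if (le[i] == "C" && pe[j] == "C") {
        h <- if (d <= 0.5) 1 else if (d >= 1.5) 0 else (1.5 - d) / 1.0
        out["hydrophobic"] <- out["hydrophobic"] + h
      }
      if (le[i] %in% c("N", "O") && pe[j] %in% c("N", "O")) {
        h <- if (d <= -0.7) 1 else if (d >= 0) 0 else -d / 0.7
        out["hbond"] <- out["hbond"] + h
      }
    }
  }
  out["nrot"] <- bfRotatableBonds(ligand)
  out
}

## brute-force X-Score-like terms
bfXscoreTerms <- function(protein, ligand) {
  pc <- coordMatrix(protein); pe <- elements(protein)
  lc <- coordMatrix(ligand); le <- elements(ligand)
  out <- c(vdw = 0, hbond = 0, hydrophobic = 0, rotor = 0)
  for (i in seq_len(nrow(lc))) {
    for (j in seq_len(nrow(pc))) {
      r <- sqrt(sum((lc[i, ] - pc[j, ])^2))
      if (r > 8) next
      d0 <- radiusOf(le[i]) + radiusOf(pe[j])
      v <- (d0 / r)^8 - 2 * (d0 / r)^4
      out["vdw"] <- out["vdw"] + min(max(v, -1), 10)
      if (le[i] %in% c("N", "O") && pe[j] %in% c("N", "O") && r <= 3.5)
        out["hbond"] <- out["hbond"] + 1
      if (le[i] == "C" && pe[j] == "C" && r <= 4.5)
        out["hydrophobic"] <- out["hydrophobic"] + 1
    }
  }
  out["rotor"] <- bfRotatableBonds(ligand)
  out
}

## brute-force connectivity after removing one edge (BFS), for ring tests
bfConnectedWithout <- function(bonds, nAtom, dropIdx) {
  adj <- vector("list", nAtom)
  for (k in seq_len(nrow(bonds))) {
    if (k == dropIdx) next
    i <- bonds$i[k]; j <- bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  from <- bonds$i[dropIdx]; to <- bonds$j[dropIdx]
  seen <- rep(FALSE, nAtom)
  queue <- from; seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  seen[to]
}

## rotatable bonds by exhaustive rule application (ring = edge in a cycle
## = endpoints still connected after removing the edge)
bfRotatableBonds <- function(mol) {
  b <- bondTable(mol)
  if (!nrow(b)) return(0L)
  deg <- tabulate(c(b$i, b$j), nbins = nAtoms(mol))
  n <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1L) next
    if (deg[b$i[k]] < 2 || deg[b$j[k]] < 2) next
    if (bfConnectedWithout(b, nAtoms(mol), k)) next  # in a ring
    n <- n + 1L
  }
  n
}

## textbook Pearson formula, evaluated directly
bfPearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## random structures for property tests (independent of the synthdata
## generator): protein atoms in a box, ligand chain-free random cloud with
## a path bond list
randomTestComplex <- function(nProt = 40, nLig = 10,
                              ligElems = LIG_ELEMS, protElems = PROT_ELEMS) {
  lc <- matrix(stats::rnorm(nLig * 3, sd = 2.5), ncol = 3)
  pc <- matrix(stats::rnorm(nProt * 3, sd = 5), ncol = 3)
  pc <- pc + matrix(rep(c(4, 0, 0), each = nProt), ncol = 3)
  bonds <- if (nLig > 1)
    data.frame(i = seq_len(nLig - 1), j = 2:nLig,
               order = sample(c(1L, 1L, 2L), nLig - 1, replace = TRUE))
  else data.frame(i = integer(0), j = integer(0), order = integer(0))
  list(protein = MolecularStructure(sample(protElems, nProt, TRUE), pc,
                                    "protein"),
       ligand = MolecularStructure(sample(ligElems, nLig, TRUE), lc,
                                   "ligand", bonds = bonds))
}

randomRotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

applyRigidMotion <- function(mol, R, t) {
  MolecularStructure(elements(mol), coordMatrix(mol) %*% R +
                       matrix(rep(t, each = nAtoms(mol)), ncol = 3),
                     structureRole(mol), bonds = bondTable(mol),
                     sourceIndex = atomTable(mol)$source_index)
}

permuteAtoms <- function(mol) {
  n <- nAtoms(mol)
  perm <- sample.int(n)
  inv <- order(perm)
  b <- bondTable(mol)
  if (nrow(b)) b <- data.frame(i = inv[b$i], j = inv[b$j], order = b$order)
  MolecularStructure(elements(mol)[perm], coordMatrix(mol)[perm, ,
                                                           drop = FALSE],
                     structureRole(mol), bonds = b)
}

## ------- text fixtures -------

pdbAtomLine <- function(serial, name, res, chain, resSeq, x, y, z,
                        element = "", record = "ATOM  ", altLoc = " ") {
  sprintf("%s%5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altLoc, res, chain, resSeq, x, y, z,
          1, 0, element)
}

molBlock <- function(elems, coords, bonds) {
  c("mol", "  test", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            length(elems), nrow(bonds)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], elems),
    if (nrow(bonds)) sprintf("%3d%3d%3d  0", bonds$i, bonds$j, bonds$order),
    "M  END", "$$$$")
}

## n-butane with explicit hydrogens: C1..C4 chain plus 10 H
butaneWithHydrogens <- function() {
  elems <- c("C", "H", "H", "H", "C", "H", "H", "C", "H", "H", "C",
             "H", "H", "H")
  coords <- matrix(0, length(elems), 3)
  cIdx <- c(1, 5, 8, 11)
  coords[cIdx, 1] <- c(0, 1.5, 3.0, 4.5)
  hs <- setdiff(seq_along(elems), cIdx)
  coords[hs, ] <- cbind(stats::runif(length(hs), -1, 6),
                        stats::runif(length(hs), 0.5, 1.5),
                        stats::runif(length(hs), 0.5, 1.5))
  bonds <- data.frame(
    i = c(1, 5, 8, 1, 1, 1, 5, 5, 8, 8, 11, 11, 11),
    j = c(5, 8, 11, 2, 3, 4, 6, 7, 9, 10, 12, 13, 14),
    order = 1L)
  molBlock(elems, coords, bonds)
}

benzeneBlock <- function() {
  ang <- 2 * pi * (0:5) / 6
  coords <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = rep(c(1L, 2L), 3))
  molBlock(rep("C", 6), coords, bonds)
}

methaneBlock <- function() {
  coords <- rbind(c(0, 0, 0), c(0.6, 0.6, 0.6), c(-0.6, -0.6, 0.6),
                  c(0.6, -0.6, -0.6), c(-0.6, 0.6, -0.6))
  bonds <- data.frame(i = rep(1L, 4), j = 2:5, order = 1L)
  molBlock(c("C", "H", "H", "H", "H"), coords, bonds)
}
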