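# Molecular-graph backend on top of OpenBabel (via ChemmineOB/ChemmineR).
#
# Everything downstream (ring systems, RECAP, fingerprints, TPSA typing)
# operates on a light molecular graph ("mg"): an atom table (element, charge,
# aromatic flag, implicit H count, ring membership) plus a bond table
# (a1, a2, order, ring/aromatic flags). Graphs are always built from the
# OpenBabel canonical SMILES so that identical molecules yield identical
# graphs, whatever the input spelling.

OB_BACKEND <- "openbabel-3.1.0"

#' Canonical SMILES via OpenBabel
#'
#' Converts SMILES strings to OpenBabel canonical form. Invalid strings raise
#' an error naming the offending input.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length and order.
#' @examples
#' canonical_smiles(c("OCC", "C(O)C"))
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (any(!nzchar(trimws(smiles)))) stop("empty SMILES string")
  tags <- paste0("m", seq_along(smiles))
  input <- paste0(paste(smiles, tags, sep = "\t", collapse = "\n"), "\n")
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", input))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) trimws(p[length(p)]), "")
  smi <- vapply(parts, function(p) p[1], "")
  res <- smi[match(tags, got)]
  if (anyNA(res)) {
    bad <- smiles[is.na(res)]
    stop("unparsable SMILES: ", paste(sQuote(bad), collapse = ", "))
  }
  unname(res)
}

# Tokenize the atoms of a SMILES string in order of appearance.
# Returns a data.frame with the element symbol and an aromatic flag per atom.
# Only used to recover aromatic perception (lowercase atoms) from OpenBabel
# canonical output; no graph is built here.
smiles_atoms <- function(smi) {
  chars <- strsplit(smi, "")[[1]]
  n <- length(chars)
  elem <- character(0); arom <- logical(0)
  i <- 1
  two_letter <- c("Cl", "Br")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) stop("unbalanced bracket in SMILES: ", smi)
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      # strip leading isotope digits
      body2 <- sub("^[0-9]+", "", body)
      m <- regmatches(body2, regexpr("^([A-Z][a-z]?|[a-z]{1,2}|\\*)", body2))
      if (!length(m)) stop("cannot read bracket atom [", body, "] in ", smi)
      sym <- m
      # 'se'/'as' are aromatic two-letter; plain lowercase else single
      if (sym %in% c("se", "as")) {
        elem <- c(elem, paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 2)))
        arom <- c(arom, TRUE)
      } else if (grepl("^[a-z]", sym)) {
        sym1 <- substr(sym, 1, 1)
        elem <- c(elem, toupper(sym1)); arom <- c(arom, TRUE)
      } else {
        elem <- c(elem, sym); arom <- c(arom, FALSE)
      }
      i <- j + 1
    } else if (i < n && paste0(ch, chars[i + 1]) %in% two_letter) {
      elem <- c(elem, paste0(ch, chars[i + 1])); arom <- c(arom, FALSE)
      i <- i + 2
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      elem <- c(elem, ch); arom <- c(arom, FALSE); i <- i + 1
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      elem <- c(elem, toupper(ch)); arom <- c(arom, TRUE); i <- i + 1
    } else if (ch == "*") {
      elem <- c(elem, "*"); arom <- c(arom, FALSE); i <- i + 1
    } else if (ch == "%") {
      i <- i + 3                       # two-digit ring closure
    } else {
      i <- i + 1                       # bonds, branches, ring digits, dots
    }
  }
  data.frame(elem = elem, aromatic = arom, stringsAsFactors = FALSE)
}

# default valence used to derive implicit hydrogen counts
.default_valence <- function(elem, charge, bondsum) {
  base <- switch(elem,
    "H" = 1, "B" = 3, "C" = 4, "N" = 3, "O" = 2, "F" = 1,
    "P" = 3, "S" = 2, "Cl" = 1, "Br" = 1, "I" = 1, "Si" = 4,
    "*" = 1, 0)
  if (elem %in% c("N", "P", "O", "S")) base <- base + charge
  if (elem == "C" && charge != 0) base <- 3
  # hypervalent S/P: bump to the next allowed valence state
  if (elem == "S" && charge == 0 && bondsum > base) base <- if (bondsum <= 4) 4 else 6
  if (elem == "P" && charge == 0 && bondsum > base) base <- 5
  if (elem == "*") base <- bondsum
  max(base, 0)
}

# molfile charge column codes -> formal charges
.chg_from_code <- function(code) {
  ifelse(code %in% 1:3, 4L - as.integer(code),
         ifelse(code %in% 5:7, 4L - as.integer(code), 0L))
}

# Parse the atom/bond block of a single V2000 molblock (text lines).
# Fallback used when ChemmineR's reader cannot cope (zero-bond molecules).
.parse_molblock <- function(lines) {
  cnt <- lines[4]
  na <- as.integer(substr(cnt, 1, 3))
  nb <- as.integer(substr(cnt, 4, 6))
  atoms <- lines[seq_len(na) + 4]
  elem <- trimws(substr(atoms, 32, 34))
  code <- suppressWarnings(as.integer(trimws(substr(atoms, 37, 39))))
  code[is.na(code)] <- 0L
  charge <- .chg_from_code(code)
  if (nb > 0) {
    bl <- lines[seq_len(nb) + 4 + na]
    bonds <- data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9)))
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  # M  CHG lines override the atom-block column
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl in chg_lines) {
    flds <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "\\s+")[[1]])
    k <- flds[1]
    for (e in seq_len(k)) charge[flds[2 * e]] <- flds[2 * e + 1]
  }
  list(elem = elem, charge = charge, bonds = bonds)
}

#' Parse a molecule into a molecular graph
#'
#' Builds the package's internal graph representation from a SMILES string.
#' The input is canonicalised first, so equal molecules give equal graphs.
#'
#' @param smiles a single SMILES string.
#' @param canonicalize canonicalise the input first (default `TRUE`; set to
#'   `FALSE` only when `smiles` is already OpenBabel-canonical).
#' @return an object of class `mol_graph`: list with `atoms` (data.frame:
#'   `elem`, `charge`, `aromatic`, `nH`, `in_ring`), `bonds` (data.frame:
#'   `a1`, `a2`, `order`, `in_ring`, `aromatic`) and `smiles`.
#' @export
parse_mol <- function(smiles, canonicalize = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  can <- if (canonicalize) canonical_smiles(smiles) else smiles
  sdf_txt <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(can, "\n")))
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  pm <- .parse_molblock(lines)
  tok <- smiles_atoms(can)
  if (nrow(tok) != length(pm$elem) ||
      !all(toupper(tok$elem) == toupper(pm$elem))) {
    stop("internal: SMILES/molblock atom order mismatch for ", can)
  }
  mg_build(pm$elem, pm$charge, tok$aromatic, pm$bonds, smiles = can)
}

# Assemble a mol_graph from parts, deriving ring membership and implicit H.
mg_build <- function(elem, charge, aromatic, bonds, smiles = NA_character_) {
  n <- length(elem)
  in_ring_atom <- rep(FALSE, n)
  bond_in_ring <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a1", "a2")]),
                                     directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    bond_in_ring <- !(seq_len(nrow(bonds)) %in% as.integer(br))
    ring_atoms <- unique(c(bonds$a1[bond_in_ring], bonds$a2[bond_in_ring]))
    in_ring_atom[ring_atoms] <- TRUE
  }
  bond_arom <- bond_in_ring & aromatic[bonds$a1] & aromatic[bonds$a2]
  bondsum <- rep(0, n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      bondsum[bonds$a1[k]] <- bondsum[bonds$a1[k]] + bonds$order[k]
      bondsum[bonds$a2[k]] <- bondsum[bonds$a2[k]] + bonds$order[k]
    }
  }
  nH <- vapply(seq_len(n), function(i) {
    max(0, .default_valence(elem[i], charge[i], bondsum[i]) - bondsum[i])
  }, numeric(1))
  structure(list(
    atoms = data.frame(elem = elem, charge = as.integer(charge),
                       aromatic = aromatic, nH = as.integer(nH),
                       in_ring = in_ring_atom, stringsAsFactors = FALSE),
    bonds = cbind(bonds, in_ring = bond_in_ring, aromatic = bond_arom),
    smiles = smiles), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, "  (", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

# Write a mol_graph (or subset of one) as a V2000 molblock string.
mg_to_molblock <- function(mg, title = "mtlkit") {
  at <- mg$atoms; bd <- mg$bonds
  na <- nrow(at); nb <- nrow(bd)
  hdr <- c(title, "  mtlkit", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, at$elem)
  bondl <- if (nb > 0)
    sprintf("%3d%3d%3d  0  0  0  0", bd$a1, bd$a2, bd$order) else character(0)
  chg <- which(at$charge != 0)
  chg_lines <- if (length(chg))
    vapply(chg, function(i) sprintf("M  CHG  1 %3d %3d", i, at$charge[i]), "")
  else character(0)
  paste(c(hdr, atoms, bondl, chg_lines, "M  END", "$$$$", ""), collapse = "\n")
}

# Canonical SMILES of a mol_graph via OpenBabel.
mg_smiles <- function(mg) {
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SDF", "CAN", mg_to_molblock(mg)))
  smi <- trimws(sub("\t.*$", "", strsplit(out, "\n", fixed = TRUE)[[1]][1]))
  if (!nzchar(smi) || is.na(smi)) stop("could not serialize molecular graph")
  smi
}

# Induced subgraph of a mol_graph on the given atom indices (1-based).
mg_subset <- function(mg, atom_idx) {
  atom_idx <- sort(unique(atom_idx))
  map <- match(seq_len(nrow(mg$atoms)), atom_idx)
  keep <- mg$bonds$a1 %in% atom_idx & mg$bonds$a2 %in% atom_idx
  bonds <- mg$bonds[keep, c("a1", "a2", "order"), drop = FALSE]
  bonds$a1 <- map[bonds$a1]; bonds$a2 <- map[bonds$a2]
  at <- mg$atoms[atom_idx, , drop = FALSE]
  mg_build(at$elem, at$charge, at$aromatic, bonds)
}

# Connected components of a mol_graph: list of atom index vectors.
mg_components <- function(mg) {
  n <- nrow(mg$atoms)
  if (nrow(mg$bonds) == 0) return(as.list(seq_len(n)))
  g <- igraph::graph_from_edgelist(as.matrix(mg$bonds[, c("a1", "a2")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  split(seq_len(n), comp)
}

# neighbours of atom i with the connecting bond rows
mg_neighbors <- function(mg, i) {
  b <- mg$bonds
  rows <- which(b$a1 == i | b$a2 == i)
  data.frame(nbr = ifelse(b$a1[rows] == i, b$a2[rows], b$a1[rows]),
             bond = rows, order = b$order[rows],
             in_ring = b$in_ring[rows], aromatic = b$aromatic[rows])
}

# number of heavy (non-H, non-dummy) atoms in a SMILES
smiles_heavy_atoms <- function(smi) {
  tok <- smiles_atoms(smi)
  sum(tok$elem != "H" & tok$elem != "*")
}

# Molecular properties from OpenBabel (formula, MW, logP, HBD, HBA, cansmi).
# One row per input molecule.
ob_properties <- function(smiles) {
  can <- canonical_smiles(smiles)
  mols <- ChemmineOB::forEachMol("SMILES",
                                 paste0(paste(can, collapse = "\n"), "\n"),
                                 identity)
  props <- do.call(rbind, lapply(mols, ChemmineOB::prop_OB))
  props$input_smiles <- smiles
  props
}

# SMARTS match counts (unique matches) for one pattern over many molecules.
smarts_count <- function(smiles, pattern) {
  can <- canonical_smiles(smiles)
  mols <- ChemmineOB::forEachMol("SMILES",
                                 paste0(paste(can, collapse = "\n"), "\n"),
                                 identity)
  vapply(seq_along(mols), function(i) {
    as.numeric(ChemmineOB::smartsSearch_OB(mols[i], pattern,
                                           uniqueMatches = TRUE))
  }, numeric(1))
}

# Does each molecule contain the SMARTS pattern at least once?
smarts_match <- function(smiles, pattern) smarts_count(smiles, pattern) > 0
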