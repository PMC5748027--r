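# Physicochemical profiling: S/P-inclusive Ertl TPSA, elemental
# composition, Cheng-Prusoff conversion, and rule-based filters
# (Lipinski, CNS, PAINS).

# Ertl fragment-contribution table (J. Med. Chem. 2000, 43, 3714), with the
# sulfur and phosphorus terms included. Each atom type is written as a
# mutually exclusive SMARTS over connectivity (X), hydrogen count (H),
# valence (v), charge, aromaticity and 3-ring membership, so a plain sum of
# match counts x contribution is exact.
tpsa_contributions <- function() {
  data.frame(
    smarts = c(
      "[NX3H0+0v3;!r3]", "[NX3H0+0v3;r3]", "[NX2H0+0v3]", "[NX1H0+0v3]",
      "[NX3H0+0v5]", "[NX2H0+0v5]", "[NX3H1+0v3;!r3]", "[NX3H1+0v3;r3]",
      "[NX2H1+0v3]", "[NX3H2+0v3]",
      "[NX4H0+1v4]", "[NX3H0+1v4]", "[NX2H0+1v4]", "[NX4H1+1v4]",
      "[NX3H1+1v4]", "[NX4H2+1v4]", "[NX3H2+1v4]", "[NX4H3+1v4]",
      "[nX2H0+0]", "[nX3H0+0;$([n](:*)(:*):*)]",
      "[nX3H0+0;$([n](-*)(:*):*)]", "[nX3H0+0;$([n](=*)(:*):*)]",
      "[nX3H1+0]", "[nX3H0+1;$([n](:*)(:*):*)]",
      "[nX3H0+1;$([n](-*)(:*):*)]", "[nX3H1+1]",
      "[OX2H0+0v2;!r3]", "[OX2H0+0v2;r3]", "[OX1H0+0v2]", "[OX2H1+0v2]",
      "[OX1H0-1v1]", "[oX2H0+0]",
      "[SX2H0+0v2]", "[SX1H0+0v2]", "[SX3H0+0v4]", "[SX4H0+0v6]",
      "[SX2H1+0v2]", "[sX2H0+0]", "[sX3H0+0;$([s]=*)]",
      "[PX3H0+0v3]", "[PX2H0+0v3]", "[PX4H0+0v5]", "[PX4H1+0v5]"),
    contribution = c(
      3.24, 3.01, 12.36, 23.79, 11.68, 13.60, 12.03, 21.94, 23.85, 26.02,
      0.00, 3.01, 4.36, 4.44, 13.97, 16.61, 25.59, 27.64,
      12.89, 4.41, 4.93, 8.39, 15.79, 4.10, 3.88, 14.14,
      9.23, 12.53, 17.07, 20.23, 23.06, 13.14,
      25.30, 32.09, 19.21, 8.38, 38.80, 28.24, 21.70,
      13.59, 34.14, 9.81, 23.47),
    stringsAsFactors = FALSE)
}

#' Topological polar surface area (S/P-inclusive)
#'
#' Ertl fragment-contribution TPSA with the sulfur and phosphorus
#' contributions included -- the dialect that reproduces values printed by
#' tools like FAFDrugs for thiophene/thiazole-bearing molecules. Additive
#' over disconnected fragments by construction.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector of TPSA values in square Angstroms.
#' @examples
#' tpsa("c1ccccc1")   # 0: no polar atoms
#' @export
tpsa <- function(smiles) {
  can <- canonical_smiles(smiles)
  mols <- ChemmineOB::forEachMol("SMILES",
                                 paste0(paste(can, collapse = "\n"), "\n"),
                                 identity)
  tab <- tpsa_contributions()
  out <- numeric(length(mols))
  for (i in seq_along(mols)) {
    counts <- vapply(tab$smarts, function(p) {
      as.numeric(ChemmineOB::smartsSearch_OB(mols[i], p,
                                             uniqueMatches = TRUE))
    }, numeric(1))
    out[i] <- sum(counts * tab$contribution)
  }
  out
}

#' IUPAC standard atomic weights
#'
#' Conventional (abridged) 2021 standard atomic weights for the elements
#' handled by the elemental-composition calculator.
#'
#' @return named numeric vector, element symbol to weight in g/mol.
#' @export
atomic_weights <- function() {
  c(H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81,
    C = 12.011, N = 14.007, O = 15.999, F = 18.998, Ne = 20.180,
    Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
    S = 32.06, Cl = 35.45, Ar = 39.95, K = 39.098, Ca = 40.078,
    Fe = 55.845, Cu = 63.546, Zn = 65.38, Se = 78.971, Br = 79.904,
    I = 126.90)
}

# "C18H19N3" -> named counts c(C=18, H=19, N=3)
parse_formula <- function(formula) {
  if (!nzchar(formula)) stop("empty formula")
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  elems <- sub("[0-9]*$", "", toks)
  counts <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  counts[is.na(counts)] <- 1L
  counts <- vapply(split(counts, elems), sum, 0L)
  counts
}

#' Calculated elemental composition
#'
#' Mass percent of each element in a molecular formula ("Analysis
#' calculated" values), reported to two decimals.
#'
#' @param formula molecular formula string (e.g. `"C18H19N3"`) or a SMILES
#'   when `from_smiles = TRUE`.
#' @param from_smiles derive the formula from a SMILES via the backend.
#' @return list with `formula` (named counts), `mw` (g/mol) and
#'   `mass_percent` (named, rounded to 2 decimals; sums to 100 within 0.01
#'   before rounding).
#' @examples
#' elemental_percent("CH4")
#' @export
elemental_percent <- function(formula, from_smiles = FALSE) {
  if (from_smiles) formula <- ob_properties(formula)$formula[1]
  counts <- parse_formula(formula)
  w <- atomic_weights()
  unknown <- setdiff(names(counts), names(w))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  masses <- counts * w[names(counts)]
  mw <- sum(masses)
  list(formula = counts, mw = mw,
       mass_percent = round(100 * masses / mw, 2))
}

#' Cheng-Prusoff conversion
#'
#' Converts a competition-binding IC50 to an inhibition constant:
#' `Ki = IC50 / (1 + C / KD)` with radioligand concentration `C` and
#' radioligand dissociation constant `KD`. Any consistent concentration
#' unit may be used; the result is in the unit of `ic50`.
#'
#' @param ic50 half-maximal inhibitory concentration (> 0).
#' @param C radioligand concentration (>= 0).
#' @param KD radioligand dissociation constant (> 0).
#' @return Ki, same unit as `ic50`; always `<= ic50`.
#' @examples
#' cheng_prusoff(1000, 1, 0.5)   # 1 uM IC50, C = 2 KD -> Ki = 1/3 uM
#' @export
cheng_prusoff <- function(ic50, C, KD) {
  if (any(ic50 <= 0)) stop("ic50 must be > 0")
  if (any(C < 0)) stop("C must be >= 0")
  if (any(KD <= 0)) stop("KD must be > 0 (zero KD is undefined)")
  ic50 / (1 + C / KD)
}

# A curated subset of the published PAINS alert families, re-expressed as
# SMARTS. This is intentionally a subset (the full catalogue has ~480
# alerts); it covers the promiscuous families most often flagged in
# screening collections.
pains_alerts <- function() {
  data.frame(
    name = c("quinone_A", "catechol_A", "rhodanine", "ene_rhodanine",
             "hydroxyphenyl_hydrazone", "alkylidene_barbiturate",
             "ene_one_ene", "azo_A", "isothiazolone", "curcumin_dienone",
             "anil_di_alk", "imine_phenol_A", "thiourea_exposed",
             "nitrobenzene_azo", "mannich_A"),
    smarts = c(
      "O=C1C=CC(=O)C=C1",
      "[OX2H1]c1ccccc1[OX2H1]",
      "S=C1[NX3]C(=O)CS1",
      "S=C1[NX3]C(=O)C(=[CX3])S1",
      "[OX2H1]c1ccccc1C=N[NX3]",
      "O=C1NC(=O)NC(=O)C1=[CX3]",
      "O=C(C=C)C=C",
      "c1ccccc1N=Nc1ccccc1",
      "O=C1C=CSN1",
      "O=C(C=Cc1ccccc1)CC(=O)C=Cc1ccccc1",
      "[NX3]([CX4])([CX4])c1ccc(cc1)C=[CX3]",
      "[OX2H1]c1ccccc1C=N[#6]",
      "[NX3H1]C(=S)[NX3H1]",
      "[O-][N+](=O)c1ccccc1N=N[#6]",
      "[OX2H1]c1ccccc1C[NX3]"),
    stringsAsFactors = FALSE)
}

#' Rule-based druglikeness filters
#'
#' Lipinski rule of 5 (MW <= 500, logP <= 5, HBD <= 5, HBA <= 10; pass if
#' at most one rule is violated), a CNS permeability filter
#' (MW <= `cns_mw`, TPSA <= `cns_tpsa` with a borderline band up to
#' `cns_tpsa_borderline`, logP <= `cns_logp`, HBD <= `cns_hbd`) and PAINS
#' substructure alerts (packaged subset, matched alert names reported).
#' logP and H-bond counts come from the chemistry backend and are named in
#' the output metadata.
#'
#' @param smiles character vector of SMILES.
#' @param cns_mw,cns_tpsa,cns_tpsa_borderline,cns_logp,cns_hbd CNS filter
#'   thresholds (defaults 450, 90, 120, 5, 3).
#' @return data.frame with descriptor columns (`mw`, `logp`, `hbd`, `hba`,
#'   `tpsa`, `rotatable_bonds`), `lipinski_pass`, `lipinski_violations`,
#'   `cns_pass`, `cns_borderline`, `cns_violations`, `pains_pass`,
#'   `pains_alerts`.
#' @export
rule_filters <- function(smiles, cns_mw = 450, cns_tpsa = 90,
                         cns_tpsa_borderline = 120, cns_logp = 5,
                         cns_hbd = 3) {
  props <- ob_properties(smiles)
  tp <- tpsa(smiles)
  rot <- smarts_count(smiles, "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]")
  n <- length(smiles)
  out <- data.frame(
    smiles = smiles, mw = props$MW, logp = props$logP, hbd = props$HBD,
    hba = props$HBA1, tpsa = tp, rotatable_bonds = as.integer(rot),
    stringsAsFactors = FALSE)
  lip_viol <- lapply(seq_len(n), function(i) {
    v <- character(0)
    if (out$mw[i] > 500) v <- c(v, "MW>500")
    if (out$logp[i] > 5) v <- c(v, "logP>5")
    if (out$hbd[i] > 5) v <- c(v, "HBD>5")
    if (out$hba[i] > 10) v <- c(v, "HBA>10")
    v
  })
  out$lipinski_violations <- vapply(lip_viol, paste, "", collapse = ";")
  out$lipinski_pass <- lengths(lip_viol) <= 1
  cns_viol <- lapply(seq_len(n), function(i) {
    v <- character(0)
    if (out$mw[i] > cns_mw) v <- c(v, sprintf("MW>%g", cns_mw))
    if (out$tpsa[i] > cns_tpsa_borderline)
      v <- c(v, sprintf("TPSA>%g", cns_tpsa_borderline))
    if (out$logp[i] > cns_logp) v <- c(v, sprintf("logP>%g", cns_logp))
    if (out$hbd[i] > cns_hbd) v <- c(v, sprintf("HBD>%g", cns_hbd))
    v
  })
  out$cns_violations <- vapply(cns_viol, paste, "", collapse = ";")
  out$cns_pass <- lengths(cns_viol) == 0
  out$cns_borderline <- out$cns_pass & out$tpsa > cns_tpsa
  alerts <- pains_alerts()
  hit_mat <- vapply(seq_len(nrow(alerts)), function(k) {
    smarts_match(smiles, alerts$smarts[k])
  }, logical(n))
  hit_mat <- matrix(hit_mat, nrow = n)
  out$pains_alerts <- vapply(seq_len(n), function(i) {
    paste(alerts$name[hit_mat[i, ]], collapse = ";")
  }, "")
  out$pains_pass <- !nzchar(out$pains_alerts)
  attr(out, "engines") <- list(logp = paste0(OB_BACKEND, "-logP"),
                               hbond = paste0(OB_BACKEND, "-HBD/HBA1"),
                               tpsa = "ertl-sp-inclusive")
  out
}

#' Full property profile
#'
#' One row per compound: descriptors, filter flags, molecular formula and
#' elemental mass percents (as a formatted string).
#'
#' @param smiles character vector of SMILES.
#' @return data.frame.
#' @export
property_profile <- function(smiles) {
  out <- rule_filters(smiles)
  props <- ob_properties(smiles)
  out$formula <- props$formula
  out$elemental <- vapply(props$formula, function(f) {
    ep <- elemental_percent(f)
    paste(sprintf("%s %.2f", names(ep$mass_percent), ep$mass_percent),
          collapse = "; ")
  }, "")
  out
}
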