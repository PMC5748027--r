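# RECAP retrosynthetic fragmentation and combinatorial recombination.
#
# Molecules are cleaved at the 11 classical retrosynthetic bond types
# (amide, ester, amine, urea, ether, olefin, quaternary N, aromatic N -
# aliphatic C, lactam N - aliphatic C, biaryl, sulfonamide). Cleavage is
# restricted to acyclic bonds; every matching bond is cut, the connected
# components become fragments whose attachment points remember the rule
# and side that created them, and recombination joins only complementary
# attachment points with the rule's bond-forming reverse reaction.
#
# Bond matching is implemented as predicates over the molecular graph.
# Each predicate receives the graph and a candidate (acyclic) bond and
# decides whether the rule cleaves it; `side1`/`side2` name the two ends
# so that only chemically sensible pairs rejoin (acyl to amine, etc.).

# helper predicates ---------------------------------------------------------

.is_carbonyl_C <- function(mg, i) {
  if (mg$atoms$elem[i] != "C" || mg$atoms$aromatic[i]) return(FALSE)
  nb <- mg_neighbors(mg, i)
  any(nb$order == 2 & mg$atoms$elem[nb$nbr] %in% c("O", "S"))
}

.is_sp3_C <- function(mg, i) {
  mg$atoms$elem[i] == "C" && !mg$atoms$aromatic[i] && {
    nb <- mg_neighbors(mg, i); all(nb$order == 1)
  }
}

.n_is_amide <- function(mg, i) {
  nb <- mg_neighbors(mg, i)
  any(vapply(nb$nbr, function(j) .is_carbonyl_C(mg, j), logical(1)))
}

.n_is_sulfonyl_adj <- function(mg, i) {
  nb <- mg_neighbors(mg, i)
  any(vapply(nb$nbr, function(j) {
    mg$atoms$elem[j] == "S" && sum(mg_neighbors(mg, j)$order == 2) >= 2
  }, logical(1)))
}

#' The RECAP rule table
#'
#' Eleven retrosynthetic bond types with the cleaved bond expressed both as
#' a SMARTS pattern (documentation) and as the graph predicate actually used
#' for matching. `bond_order` is the order of the bond reformed on
#' recombination (2 for the olefin rule, 1 otherwise); `symmetric` marks
#' rules whose two ends are interchangeable.
#'
#' @return data.frame with columns `name`, `bond_smarts`, `side1`, `side2`,
#'   `bond_order`, `symmetric`.
#' @export
recap_rules <- function() {
  data.frame(
    name = c("amide", "ester", "amine", "urea", "ether", "olefin",
             "quaternary_N", "aromatic_N_aliphatic_C",
             "lactam_N_aliphatic_C", "biaryl", "sulfonamide"),
    bond_smarts = c(
      "[C;!a](=O)-[N;!a]", "[C;!a](=O)-[OX2]", "[NX3;!$(NC=O);!a]-[CX4]",
      "[NX3]-[C](=O)-[NX3]", "[OX2;!$(OC=O)]([#6])-[CX4]", "C=C",
      "[N+X4]-[C]", "[n]-[CX4]", "[N;R;$(NC=O)]-[CX4;!R]", "c-c",
      "[SX4](=O)(=O)-[NX3]"),
    side1 = c("acyl", "acyl", "amine_N", "urea_N", "ether_O", "olefin_C",
              "quat_N", "aromatic_N", "lactam_N", "aryl", "sulfonyl"),
    side2 = c("amide_N", "ester_O", "amine_C", "urea_C", "ether_C",
              "olefin_C", "quat_C", "aliphatic_C", "lactam_C", "aryl",
              "amide_N"),
    bond_order = c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L),
    symmetric = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                  FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

# Try to match rule `rule` on bond k of mg. Returns NULL or a list
# (rule, atom_side1, atom_side2).
.match_rule <- function(mg, k, rule) {
  b <- mg$bonds[k, ]
  a <- b$a1; c <- b$a2
  at <- mg$atoms
  try_orient <- function(i, j) {
    switch(rule,
      amide = if (b$order == 1 && .is_carbonyl_C(mg, i) &&
                  at$elem[j] == "N" && !at$aromatic[j] &&
                  !.n_is_sulfonyl_adj(mg, j) && !at$in_ring[j] &&
                  # urea N-C(=O) handled by its own rule
                  !{nb <- mg_neighbors(mg, i)
                    sum(at$elem[nb$nbr] == "N" & nb$order == 1) >= 2})
        list(i, j),
      ester = if (b$order == 1 && .is_carbonyl_C(mg, i) &&
                  at$elem[j] == "O" && !at$aromatic[j]) list(i, j),
      amine = if (b$order == 1 && at$elem[i] == "N" && !at$aromatic[i] &&
                  at$charge[i] == 0 && !.n_is_amide(mg, i) &&
                  !.n_is_sulfonyl_adj(mg, i) && .is_sp3_C(mg, j))
        list(i, j),
      urea = if (b$order == 1 && at$elem[i] == "N" && !at$aromatic[i] &&
                 .is_carbonyl_C(mg, j) && {
                   nb <- mg_neighbors(mg, j)
                   sum(at$elem[nb$nbr] == "N" & nb$order == 1) >= 2
                 }) list(i, j),
      ether = if (b$order == 1 && at$elem[i] == "O" && !at$aromatic[i] &&
                  !{nb <- mg_neighbors(mg, i)
                    any(vapply(nb$nbr, function(x) .is_carbonyl_C(mg, x),
                               logical(1)))} &&
                  {nb <- mg_neighbors(mg, i)
                   all(at$elem[nb$nbr] == "C")} && length(mg_neighbors(mg, i)$nbr) == 2 &&
                  .is_sp3_C(mg, j)) list(i, j),
      olefin = if (b$order == 2 && at$elem[i] == "C" && at$elem[j] == "C" &&
                   !at$aromatic[i] && !at$aromatic[j]) list(i, j),
      quaternary_N = if (b$order == 1 && at$elem[i] == "N" &&
                         at$charge[i] == 1 &&
                         nrow(mg_neighbors(mg, i)) == 4 &&
                         at$elem[j] == "C") list(i, j),
      aromatic_N_aliphatic_C = if (b$order == 1 && at$elem[i] == "N" &&
                                   at$aromatic[i] && .is_sp3_C(mg, j))
        list(i, j),
      lactam_N_aliphatic_C = if (b$order == 1 && at$elem[i] == "N" &&
                                 !at$aromatic[i] && at$in_ring[i] &&
                                 .n_is_amide(mg, i) && .is_sp3_C(mg, j) &&
                                 !at$in_ring[j]) list(i, j),
      biaryl = if (b$order == 1 && at$aromatic[i] && at$aromatic[j] &&
                   at$elem[i] == "C" && at$elem[j] == "C") list(i, j),
      sulfonamide = if (b$order == 1 && at$elem[i] == "S" &&
                        sum(mg_neighbors(mg, i)$order == 2) >= 2 &&
                        at$elem[j] == "N" && !at$aromatic[j]) list(i, j))
  }
  m <- try_orient(a, c)
  if (is.null(m)) m <- try_orient(c, a)
  if (is.null(m)) return(NULL)
  list(rule = rule, s1 = m[[1]], s2 = m[[2]])
}

# All cleavable (acyclic) bonds of mg under the given rules. More specific
# rules win when several match the same bond (urea before amide before
# amine; lactam before aromatic-N; sulfonamide checked before amide by the
# amide predicate itself).
.cleavable_bonds <- function(mg, rules = recap_rules()$name) {
  order_pref <- c("urea", "sulfonamide", "amide", "ester",
                  "lactam_N_aliphatic_C", "aromatic_N_aliphatic_C",
                  "quaternary_N", "amine", "ether", "olefin", "biaryl")
  rules <- order_pref[order_pref %in% rules]
  out <- list()
  for (k in seq_len(nrow(mg$bonds))) {
    if (mg$bonds$in_ring[k]) next
    for (r in rules) {
      m <- .match_rule(mg, k, r)
      if (!is.null(m)) {
        out[[length(out) + 1]] <- list(bond = k, rule = r,
                                       s1 = m$s1, s2 = m$s2)
        break
      }
    }
  }
  out
}

#' Fragment a molecule at RECAP bonds
#'
#' Cuts every cleavable bond (recursively equivalent: cleavage never creates
#' new cleavable bonds) and returns the fragment pool. Each attachment point
#' carries the rule and side that created it. Fragments smaller than
#' `min_heavy_atoms` heavy atoms are discarded.
#'
#' @param smiles a single SMILES string.
#' @param min_heavy_atoms minimum fragment size in heavy atoms (default 3).
#' @param rules subset of rule names from [recap_rules()] to apply.
#' @param parent_id provenance label stored on each fragment.
#' @return an object of class `recap_pool`: a list of fragments, each a list
#'   with `smiles` (attachment points as `[*]`), `mg`, and `attachments`
#'   (data.frame `atom`, `rule`, `side`, `bond_order`). Molecules with no
#'   cleavable bond give an empty pool.
#' @export
recap_fragment <- function(smiles, min_heavy_atoms = 3,
                           rules = recap_rules()$name, parent_id = smiles) {
  mg <- parse_mol(smiles)
  cuts <- .cleavable_bonds(mg, rules)
  if (!length(cuts)) {
    return(structure(list(), class = "recap_pool"))
  }
  rule_tab <- recap_rules()
  cut_bonds <- vapply(cuts, `[[`, 0, "bond")
  keep <- setdiff(seq_len(nrow(mg$bonds)), cut_bonds)
  residual <- mg_build(mg$atoms$elem, mg$atoms$charge, mg$atoms$aromatic,
                       mg$bonds[keep, c("a1", "a2", "order"), drop = FALSE])
  comps <- mg_components(residual)
  frags <- list()
  for (comp in comps) {
    heavy <- sum(mg$atoms$elem[comp] != "H")
    if (heavy < min_heavy_atoms) next
    att <- data.frame(atom = integer(0), rule = character(0),
                      side = character(0), bond_order = integer(0),
                      stringsAsFactors = FALSE)
    for (cut in cuts) {
      ri <- rule_tab[rule_tab$name == cut$rule, ]
      if (cut$s1 %in% comp) {
        att <- rbind(att, data.frame(atom = cut$s1, rule = cut$rule,
                                     side = ri$side1,
                                     bond_order = ri$bond_order))
      }
      if (cut$s2 %in% comp) {
        att <- rbind(att, data.frame(atom = cut$s2, rule = cut$rule,
                                     side = ri$side2,
                                     bond_order = ri$bond_order))
      }
    }
    frags[[length(frags) + 1]] <- .make_fragment(mg, comp, att, parent_id)
  }
  structure(frags, class = "recap_pool")
}

# Build a fragment object: subgraph + dummy atoms at attachment points.
.make_fragment <- function(mg, comp, att, parent_id) {
  comp <- sort(comp)
  sub <- mg_subset(mg, comp)
  att$atom_local <- match(att$atom, comp)
  n0 <- nrow(sub$atoms)
  elem <- c(sub$atoms$elem, rep("*", nrow(att)))
  charge <- c(sub$atoms$charge, rep(0L, nrow(att)))
  arom <- c(sub$atoms$aromatic, rep(FALSE, nrow(att)))
  bonds <- rbind(sub$bonds[, c("a1", "a2", "order")],
                 data.frame(a1 = att$atom_local,
                            a2 = n0 + seq_len(nrow(att)),
                            order = att$bond_order))
  mgf <- mg_build(elem, charge, arom, bonds)
  att_out <- data.frame(atom = att$atom_local, dummy = n0 + seq_len(nrow(att)),
                        rule = att$rule, side = att$side,
                        bond_order = att$bond_order,
                        stringsAsFactors = FALSE)
  list(smiles = mg_smiles(mgf), mg = mgf, attachments = att_out,
       parent_id = parent_id)
}

#' @export
print.recap_pool <- function(x, ...) {
  cat("<recap_pool> ", length(x), " fragment(s)\n", sep = "")
  for (f in x) {
    cat("  ", f$smiles, "  [",
        paste(paste(f$attachments$rule, f$attachments$side, sep = "/"),
              collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}

#' Merge fragment pools
#'
#' @param ... `recap_pool` objects.
#' @return a single `recap_pool`.
#' @export
merge_pools <- function(...) {
  structure(do.call(c, lapply(list(...), unclass)), class = "recap_pool")
}

# join fragment f1 at attachment i1 with f2 at attachment i2
.join_fragments <- function(f1, i1, f2, i2) {
  a1 <- f1$attachments[i1, ]; a2 <- f2$attachments[i2, ]
  n1 <- nrow(f1$mg$atoms)
  elem <- c(f1$mg$atoms$elem, f2$mg$atoms$elem)
  charge <- c(f1$mg$atoms$charge, f2$mg$atoms$charge)
  arom <- c(f1$mg$atoms$aromatic, f2$mg$atoms$aromatic)
  b2 <- f2$mg$bonds[, c("a1", "a2", "order")]
  b2$a1 <- b2$a1 + n1; b2$a2 <- b2$a2 + n1
  bonds <- rbind(f1$mg$bonds[, c("a1", "a2", "order")], b2,
                 data.frame(a1 = a1$atom, a2 = a2$atom + n1,
                            order = a1$bond_order))
  drop <- c(a1$dummy, a2$dummy + n1,
            f1$attachments$dummy[-i1], f2$attachments$dummy[-i2] + n1)
  keep <- setdiff(seq_along(elem), drop)   # unused attachments H-capped
  bonds <- bonds[bonds$a1 %in% keep & bonds$a2 %in% keep, , drop = FALSE]
  map <- match(seq_along(elem), keep)
  bonds$a1 <- map[bonds$a1]; bonds$a2 <- map[bonds$a2]
  mg_build(elem[keep], charge[keep], arom[keep], bonds)
}

#' Check rule symmetry: cleave one bond, rejoin, recover the parent
#'
#' For every cleavable bond of the molecule, cuts exactly that bond, rejoins
#' the two fragments with the rule's bond-forming reverse reaction, and
#' compares the result with the parent's canonical SMILES. This is the
#' invariant that every rule's reverse regenerates the bond it cleaves.
#'
#' @param smiles a single SMILES string.
#' @param rules subset of rule names from [recap_rules()] to apply.
#' @return named logical vector, one entry per cleavable bond (named by
#'   rule); `logical(0)` when no bond is cleavable.
#' @export
recap_roundtrip <- function(smiles, rules = recap_rules()$name) {
  mg <- parse_mol(smiles)
  can <- mg$smiles
  cuts <- .cleavable_bonds(mg, rules)
  if (!length(cuts)) return(logical(0))
  rule_tab <- recap_rules()
  out <- vapply(cuts, function(cut) {
    ri <- rule_tab[rule_tab$name == cut$rule, ]
    keep <- setdiff(seq_len(nrow(mg$bonds)), cut$bond)
    residual <- mg_build(mg$atoms$elem, mg$atoms$charge, mg$atoms$aromatic,
                         mg$bonds[keep, c("a1", "a2", "order"),
                                  drop = FALSE])
    comps <- mg_components(residual)
    c1 <- which(vapply(comps, function(x) cut$s1 %in% x, logical(1)))
    c2 <- which(vapply(comps, function(x) cut$s2 %in% x, logical(1)))
    f1 <- .make_fragment(mg, comps[[c1]],
                         data.frame(atom = cut$s1, rule = cut$rule,
                                    side = ri$side1,
                                    bond_order = ri$bond_order),
                         smiles)
    f2 <- .make_fragment(mg, comps[[c2]],
                         data.frame(atom = cut$s2, rule = cut$rule,
                                    side = ri$side2,
                                    bond_order = ri$bond_order),
                         smiles)
    identical(mg_smiles(.join_fragments(f1, 1, f2, 1)), can)
  }, logical(1))
  names(out) <- vapply(cuts, `[[`, "", "rule")
  out
}

#' Recombine a fragment pool into a candidate library
#'
#' Joins every compatible pair of attachment points: same rule, and
#' complementary sides (or either end for the symmetric olefin/biaryl
#' rules). Unused attachment points are capped with hydrogen. Products are
#' sanitized by the backend, canonicalized and deduplicated; products
#' identical to an input parent are flagged, not dropped. When the full
#' enumeration would exceed `max_products`, a seed-determined uniform sample
#' of pairs is taken.
#'
#' @param pool a `recap_pool`.
#' @param max_products cap on enumerated products (>= 1).
#' @param seed integer seed for the subsampling draw.
#' @param parents canonical SMILES of the parent molecules, used to flag
#'   regenerated parents.
#' @return data.frame with columns `id`, `smiles` (canonical), `frag1`,
#'   `frag2`, `rule`, `is_parent`; attribute `n_invalid` counts joins
#'   rejected at sanitization.
#' @export
recap_recombine <- function(pool, max_products = 10000, seed = 1,
                            parents = character()) {
  if (max_products < 1) stop("max_products must be >= 1")
  if (!length(pool)) {
    return(data.frame(id = character(0), smiles = character(0),
                      frag1 = character(0), frag2 = character(0),
                      rule = character(0), is_parent = logical(0)))
  }
  # enumerate attachment points
  pts <- do.call(rbind, lapply(seq_along(pool), function(fi) {
    att <- pool[[fi]]$attachments
    data.frame(frag = fi, att = seq_len(nrow(att)), rule = att$rule,
               side = att$side, stringsAsFactors = FALSE)
  }))
  rule_tab <- recap_rules()
  pairs <- list()
  for (r in unique(pts$rule)) {
    ri <- rule_tab[rule_tab$name == r, ]
    p <- pts[pts$rule == r, , drop = FALSE]
    if (ri$symmetric) {
      idx <- which(upper.tri(matrix(0, nrow(p), nrow(p))), arr.ind = TRUE)
      if (nrow(idx)) pairs[[r]] <- data.frame(
        i = p$frag[idx[, 1]], ai = p$att[idx[, 1]],
        j = p$frag[idx[, 2]], aj = p$att[idx[, 2]], rule = r)
    } else {
      s1 <- p[p$side == ri$side1, , drop = FALSE]
      s2 <- p[p$side == ri$side2, , drop = FALSE]
      if (nrow(s1) && nrow(s2)) {
        grid <- expand.grid(x = seq_len(nrow(s1)), y = seq_len(nrow(s2)))
        pairs[[r]] <- data.frame(
          i = s1$frag[grid$x], ai = s1$att[grid$x],
          j = s2$frag[grid$y], aj = s2$att[grid$y], rule = r)
      }
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || !nrow(pairs)) {
    return(data.frame(id = character(0), smiles = character(0),
                      frag1 = character(0), frag2 = character(0),
                      rule = character(0), is_parent = logical(0)))
  }
  # self-joins of one physical attachment point are impossible
  pairs <- pairs[!(pairs$i == pairs$j & pairs$ai == pairs$aj), , drop = FALSE]
  if (nrow(pairs) > max_products) {
    withr_seed <- seed %% .Machine$integer.max
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(withr_seed)
    pairs <- pairs[sort(sample.int(nrow(pairs), max_products)), , drop = FALSE]
  }
  n_invalid <- 0L
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    pr <- pairs[k, ]
    smi <- tryCatch({
      mgp <- .join_fragments(pool[[pr$i]], pr$ai, pool[[pr$j]], pr$aj)
      mg_smiles(mgp)
    }, error = function(e) NA_character_)
    if (is.na(smi)) { n_invalid <- n_invalid + 1L; next }
    rows[[k]] <- data.frame(
      smiles = smi, frag1 = pool[[pr$i]]$smiles, frag2 = pool[[pr$j]]$smiles,
      rule = pr$rule, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    out <- data.frame(smiles = character(0), frag1 = character(0),
                      frag2 = character(0), rule = character(0))
  }
  out <- out[!duplicated(out$smiles), , drop = FALSE]
  out$id <- paste0("recap", seq_len(nrow(out)))
  parents_can <- if (length(parents)) canonical_smiles(parents) else character(0)
  out$is_parent <- out$smiles %in% parents_can
  out <- out[, c("id", "smiles", "frag1", "frag2", "rule", "is_parent")]
  attr(out, "n_invalid") <- n_invalid
  rownames(out) <- NULL
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Focus a candidate library on required frameworks
#'
#' Keeps candidates containing at least one of the required ring-system
#' frameworks as a substructure (matched as SMARTS). An empty framework set
#' returns the library unchanged with a warning.
#'
#' @param library data.frame with a `smiles` column (from
#'   [recap_recombine()]).
#' @param frameworks character vector of framework SMILES/SMARTS.
#' @return the filtered library (provenance columns preserved).
#' @export
focus_library <- function(library, frameworks) {
  if (!length(frameworks)) {
    warning("empty framework set: returning library unchanged")
    return(library)
  }
  if (!nrow(library)) return(library)
  keep <- rep(FALSE, nrow(library))
  for (f in frameworks) keep <- keep | smarts_match(library$smiles, f)
  library[keep, , drop = FALSE]
}
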