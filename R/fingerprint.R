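# Circular (Morgan/ECFP-style) fingerprints of radius 2, folded to a fixed
# number of bits. Implemented directly on the molecular graph so that the
# environment enumeration follows the conventional definition: one feature
# per distinct atom environment, where an environment that stops growing
# (terminal atoms) contributes no further features, and environments with
# identical bond sets are counted once. Hashing is a polynomial rolling
# hash modulo 2^31 - 1, exact in double precision; folding is hash modulo
# the bit-vector length.

.HASH_P <- 2147483647  # 2^31 - 1

.hash_ints <- function(x) {
  h <- 5381
  for (v in x) h <- (h * 33 + (v %% .HASH_P)) %% .HASH_P
  h
}

.elem_number <- function(elem) {
  tab <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
           S = 16, Cl = 17, Br = 35, I = 53, `*` = 0)
  out <- unname(tab[elem])
  out[is.na(out)] <- 99
  out
}

#' Circular fingerprint of a molecule
#'
#' ECFP4-equivalent binary fingerprint: initial atom invariants are
#' (atomic number, heavy degree, total H count, formal charge, ring flag,
#' aromatic flag); neighbourhoods are grown to `radius` bond iterations,
#' each new environment is hashed and the hash folded into `n_bits` bits.
#' Identical canonical SMILES give identical bits.
#'
#' @param smiles character vector of SMILES.
#' @param n_bits fingerprint length (default 2048).
#' @param radius maximum environment radius in bonds (default 2, i.e.
#'   diameter 4).
#' @return binary matrix, one row per molecule, `n_bits` columns.
#' @examples
#' sum(morgan_fp("C"))     # methane: a single atom environment
#' @export
morgan_fp <- function(smiles, n_bits = 2048, radius = 2) {
  stopifnot(n_bits >= 2, radius >= 0)
  can <- canonical_smiles(smiles)
  out <- matrix(0L, nrow = length(can), ncol = n_bits)
  for (m in seq_along(can)) {
    mg <- parse_mol(can[m], canonicalize = FALSE)
    out[m, .morgan_bits(mg, n_bits, radius)] <- 1L
  }
  rownames(out) <- names(smiles)
  out
}

.morgan_bits <- function(mg, n_bits, radius) {
  at <- mg$atoms
  n <- nrow(at)
  nbrs <- lapply(seq_len(n), function(i) mg_neighbors(mg, i))
  deg <- vapply(nbrs, nrow, 0)
  ids <- vapply(seq_len(n), function(i) {
    .hash_ints(c(.elem_number(at$elem[i]), deg[i], at$nH[i],
                 at$charge[i] + 10, as.integer(at$in_ring[i]),
                 as.integer(at$aromatic[i])))
  }, numeric(1))
  # bond type code: aromatic ring bonds hash identically whatever the
  # kekule assignment of the canonical form
  bcode <- ifelse(mg$bonds$aromatic, 4L, mg$bonds$order)
  feats <- ids                      # radius-0 features
  env <- lapply(seq_len(n), function(i) integer(0))
  seen_env <- character(0)
  for (r in seq_len(radius)) {
    new_ids <- numeric(n)
    new_env <- vector("list", n)
    for (i in seq_len(n)) {
      nb <- nbrs[[i]]
      if (!nrow(nb)) { new_ids[i] <- ids[i]; new_env[[i]] <- env[[i]]; next }
      ord <- order(bcode[nb$bond], ids[nb$nbr])
      pairs <- as.vector(rbind(bcode[nb$bond][ord], ids[nb$nbr][ord]))
      new_ids[i] <- .hash_ints(c(r, ids[i], pairs))
      new_env[[i]] <- sort(unique(c(env[[i]], nb$bond,
                                    unlist(env[nb$nbr]))))
    }
    for (i in seq_len(n)) {
      grew <- !identical(new_env[[i]], env[[i]])
      key <- paste(new_env[[i]], collapse = ",")
      if (grew && !(key %in% seen_env)) {
        feats <- c(feats, new_ids[i])
        seen_env <- c(seen_env, key)
      }
    }
    ids <- new_ids
    env <- new_env
  }
  unique(as.integer(feats %% n_bits) + 1L)
}
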