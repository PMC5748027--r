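test_that("molecules without cleavable bonds give an empty pool", {
  expect_length(recap_fragment("CC"), 0)
  expect_length(recap_fragment("c1ccccc1"), 0)
})

test_that("acetanilide cleaves into acetyl and anilino fragments", {
  pool <- recap_fragment("CC(=O)Nc1ccccc1", min_heavy_atoms = 2)
  expect_length(pool, 2)
  smi <- vapply(pool, `[[`, "", "smiles")
  expect_setequal(smi, c("*C(=O)C", "*Nc1ccccc1"))
  rules <- unlist(lapply(pool, function(f) f$attachments$rule))
  expect_true(all(rules == "amide"))
  sides <- unlist(lapply(pool, function(f) f$attachments$side))
  expect_setequal(sides, c("acyl", "amide_N"))
})

test_that("cleave-then-rejoin is the identity on every corpus molecule", {
  for (smi in recap_corpus()) {
    rt <- recap_roundtrip(smi)
    expect_gt(length(rt), 0, label = paste("cleavable bonds of", smi))
    expect_true(all(rt), info = smi)
  }
})

test_that("pool recombination regenerates singly-cut parents", {
  for (smi in c("CC(=O)Nc1ccccc1", "c1ccccc1-c1ccncc1", "Cn1cccc1")) {
    can <- canonical_smiles(smi)
    pool <- recap_fragment(smi, min_heavy_atoms = 1)
    lib <- recap_recombine(pool, max_products = 5000, seed = 1,
                           parents = smi)
    expect_true(can %in% lib$smiles, info = smi)
    expect_true(any(lib$is_parent[lib$smiles == can]), info = smi)
  }
})

test_that("fragments of recombined products stay within the parent's pool", {
  # holds for products of two single-attachment fragments; a fragment with
  # leftover attachment points gets those H-capped in the product, which
  # legitimately changes its fragmentation
  for (smi in recap_corpus()) {
    pool <- recap_fragment(smi, min_heavy_atoms = 1)
    single <- Filter(function(f) nrow(f$attachments) == 1, pool)
    if (length(single) < 2) next
    pool1 <- structure(single, class = "recap_pool")
    frag_smi <- vapply(pool1, `[[`, "", "smiles")
    lib <- recap_recombine(pool1, max_products = 200, seed = 1)
    for (prod in lib$smiles) {
      sub <- recap_fragment(prod, min_heavy_atoms = 1)
      sub_smi <- vapply(sub, `[[`, "", "smiles")
      expect_true(all(sub_smi %in% frag_smi),
                  info = paste(smi, "->", prod))
    }
  }
})

test_that("cross-pool recombination respects the n x m counting bound", {
  # n acyl fragments x m amine fragments, one amide attachment each
  acyls <- c("CC(=O)Nc1ccccc1", "CCC(=O)Nc1ccccc1", "CCCC(=O)Nc1ccccc1")
  pools <- lapply(acyls, recap_fragment, min_heavy_atoms = 2)
  pool <- do.call(merge_pools, pools)
  pts <- do.call(rbind, lapply(pool, `[[`, "attachments"))
  n_acyl <- sum(pts$side == "acyl")
  n_amine <- sum(pts$side == "amide_N")
  lib <- recap_recombine(pool, max_products = 10000, seed = 1)
  # before dedup: n x m pairings; after dedup, at most that many
  expect_lte(nrow(lib), n_acyl * n_amine)
  # dedup equals the set-of-canonical-SMILES oracle
  expect_equal(nrow(lib), length(unique(lib$smiles)))
  expect_false(anyDuplicated(lib$smiles) > 0)
})

test_that("every recombination product passes sanitization", {
  fx <- the_fixtures()
  smi <- utils::head(unique(fx$compounds$smiles), 25)
  pool <- do.call(merge_pools, lapply(smi, recap_fragment))
  lib <- recap_recombine(pool, max_products = 150, seed = 3)
  expect_gt(nrow(lib), 0)
  for (s in lib$smiles) expect_silent(canonical_smiles(s))
  expect_true(is.numeric(attr(lib, "n_invalid")))
})

test_that("recombination is deterministic given the seed", {
  fx <- the_fixtures()
  smi <- utils::head(unique(fx$compounds$smiles), 15)
  pool <- do.call(merge_pools, lapply(smi, recap_fragment))
  l1 <- recap_recombine(pool, max_products = 50, seed = 9)
  l2 <- recap_recombine(pool, max_products = 50, seed = 9)
  expect_identical(l1, l2)
  expect_error(recap_recombine(pool, max_products = 0), "max_products")
})

test_that("focus_library keeps exactly the framework-bearing candidates", {
  pyr <- canonical_smiles("c1ccncc1")
  lib <- data.frame(
    id = paste0("c", 1:5),
    smiles = c("CCc1ccncc1", "CCCCCC", "c1ccncc1C(=O)NC",
               "C1CCCCC1", "CCOc1ccccc1"),
    stringsAsFactors = FALSE)
  out <- focus_library(lib, pyr)
  expect_equal(out$id, c("c1", "c3"))
  expect_warning(out2 <- focus_library(lib, character(0)), "unchanged")
  expect_equal(nrow(out2), 5)
})

test_that("focused fraction recovers a planted composition exactly", {
  with_core <- paste0(c("CC", "CCC", "CCCC"), "c1ccncc1")
  without <- c("CCCCCC", "C1CCCCC1", "c1ccccc1CC", "CCOCC",
               "CC(C)CC", "c1ccc2ccccc2c1", "CCCCO")
  lib <- data.frame(id = paste0("x", 1:10),
                    smiles = c(with_core, without))
  out <- focus_library(lib, canonical_smiles("c1ccncc1"))
  expect_equal(nrow(out) / nrow(lib), 0.3)
})

test_that("the rule table round-trips each bond type it declares", {
  rules <- recap_rules()
  expect_equal(nrow(rules), 11)
  expect_setequal(rules$bond_order, c(1L, 2L))
  # olefin: double bond reformed on rejoin
  pool <- recap_fragment("CCC=CCC", min_heavy_atoms = 1)
  expect_length(pool, 2)
  lib <- recap_recombine(pool, parents = "CCC=CCC")
  expect_true(canonical_smiles("CCC=CCC") %in% lib$smiles)
})
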