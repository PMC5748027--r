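test_that("ring systems: acyclic, multi-ring, and fused cases", {
  expect_length(extract_ring_systems("CCCCCC"), 0)
  # 2-amino-4-cyclohexyl-6-phenylpyridine-3-carbonitrile:
  # pyridine + benzene + cyclohexane, substituents stripped
  rs <- extract_ring_systems("Nc1nc(-c2ccccc2)cc(C2CCCCC2)c1C#N")
  expect_setequal(rs, canonical_smiles(c("c1ccncc1", "c1ccccc1",
                                         "C1CCCCC1")))
  # caffeine keeps the fused bicyclic (xanthine) as one framework with its
  # exocyclic carbonyls, not two separate rings
  caff <- extract_ring_systems("Cn1cnc2c1c(=O)n(C)c(=O)n2C")
  expect_length(caff, 1)
  # stripping different N-methylation patterns gives the same xanthine core
  theobromine <- extract_ring_systems("Cn1cnc2c1c(=O)[nH]c(=O)n2C")
  expect_equal(caff, theobromine)
  # the retained core still carries both exocyclic carbonyl oxygens
  expect_equal(sum(mtlkit:::smiles_atoms(caff)$elem == "O"), 2)
})

test_that("every framework is a substructure of its parent", {
  for (smi in corpus_smiles()) {
    for (f in extract_ring_systems(smi)) {
      # stripped substituent positions gain an H in the framework, so the
      # substructure check must be H-agnostic at aromatic nitrogens
      query <- gsub("[nH]", "n", f, fixed = TRUE)
      expect_true(mtlkit:::smarts_match(smi, query),
                  info = paste(smi, "->", f))
    }
  }
})

test_that("frequency ranking counts, truncates and breaks ties", {
  smi <- c("c1ccncc1C", "c1ccncc1CC", "CCc1ccncc1", "c1ccoc1C")
  rk <- frequency_rank(smi, top_k = 30)
  expect_equal(rk$framework[1], canonical_smiles("c1ccncc1"))
  expect_equal(rk$count[1], 3)
  # tie: furan vs a second singleton framework -> lexicographic order
  smi2 <- c("c1ccoc1C", "Cc1ccsc1")
  rk2 <- frequency_rank(smi2)
  expect_equal(rk2$count, c(1, 1))
  expect_equal(rk2$framework, sort(rk2$framework))
  expect_equal(rk2$rank, 1:2)
  expect_error(frequency_rank(smi, top_k = 0), "top_k")
})

test_that("frequency ranking equals a dictionary-count oracle", {
  fx <- the_fixtures()
  smi <- fx$compounds$smiles[fx$compounds$target == "A1R"]
  rk <- frequency_rank(smi, top_k = 100)
  oracle <- table(unlist(lapply(smi, extract_ring_systems)))
  for (i in seq_len(nrow(rk))) {
    expect_equal(rk$count[i], unname(oracle[rk$framework[i]]))
  }
  expect_false(is.unsorted(rev(rk$count)))
})

test_that("common heterocycles: intersection, whitelist, empty cases", {
  pyr <- canonical_smiles("c1ccncc1"); pym <- canonical_smiles("c1cncnc1")
  rank_of <- function(fws) data.frame(framework = fws,
                                      count = rev(seq_along(fws)),
                                      rank = seq_along(fws))
  shared <- list(t1 = rank_of(c(pyr, pym)), t2 = rank_of(c(pym, pyr)))
  expect_setequal(common_heterocycles(shared), c(pyr, pym))
  disjoint <- list(t1 = rank_of(pyr), t2 = rank_of(pym))
  expect_warning(out <- common_heterocycles(disjoint), "no common")
  expect_length(out, 0)
  # whitelist is always carried along (e.g. purine for A1/A2A only)
  purine <- "c1ncc2[nH]cnc2n1"
  out2 <- common_heterocycles(disjoint, whitelist = purine)
  expect_equal(out2, canonical_smiles(purine))
  expect_error(common_heterocycles(shared[1]), ">= 2 targets")
})

test_that("three planted rankings intersect to the planted common set", {
  fx <- the_fixtures()
  ranked <- lapply(split(fx$compounds, fx$compounds$target),
                   function(df) frequency_rank(df$smiles, top_k = 30))
  common <- common_heterocycles(ranked, top_k = 30)
  planted_common <- canonical_smiles(unlist(
    fx$ground_truth$core_smiles[c("pyridine", "pyrimidine", "piperazine",
                                  "pyrazole")]))
  expect_true(all(planted_common %in% common))
  # adenosine-specific cores are not in the three-way intersection
  purine <- canonical_smiles(fx$ground_truth$core_smiles$purine)
  expect_false(purine %in% common)
})

test_that("series frequencies: fractions, other bucket, planted mix", {
  series <- default_series()
  apc <- "Nc1nc(-c2ccccc2)cc(C2CCCCC2)c1C#N"    # aminopyridine-carbonitrile
  tq <- "Nc1nc2ccccc2c2nc(-c3ccco3)nn12"        # triazoloquinazoline
  iq <- "c1ccc2c(c1)n1cncc1cn2"                 # imidazoquinoxaline
  aiq <- "COc1cc2ccncc2cc1OC"                   # 6,7-dialkoxyisoquinoline
  none <- "CCCCCC"
  smi <- c(rep(apc, 5), rep(tq, 2), iq, aiq, none)
  sf <- series_frequencies(smi, series)
  expect_equal(sf$fraction[sf$series == "aminopyridine_carbonitrile"], 0.5)
  expect_equal(sf$fraction[sf$series == "triazoloquinazoline"], 0.2)
  expect_equal(sf$count[sf$series == "other"], 1)
  # packaged series are mutually exclusive: counts + other = total
  expect_equal(sum(sf$count), length(smi))
  expect_error(series_frequencies(character(0)), "no candidates")
})
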