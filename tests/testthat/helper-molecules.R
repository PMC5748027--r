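# Shared molecule corpora and a cached small fixture bundle.

# a mixed corpus exercising charges, fragments, heteroaromatics
corpus_smiles <- function() {
  c("CCO", "c1ccccc1", "Nc1nc(-c2ccccc2)cc(C2CCCCC2)c1C#N",
    "CC(=O)Nc1ccccc1", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    "CC(=O)[O-]", "CC[NH3+]", "c1ccc2ccccc2c1", "CCOCC",
    "CCS(=O)(=O)Nc1ccccc1", "O=C(NC1CC1)c1ccncc1",
    "COc1ccc(CNC(C)=O)cc1", "c1cc[nH]n1", "C1CNCCN1")
}

# molecules with at least one RECAP-cleavable bond, used for round trips
recap_corpus <- function() {
  c("CC(=O)Nc1ccccc1",                 # amide
    "CC(=O)OCCc1ccccc1",               # ester
    "CCNC1CCCCC1",                     # amine
    "CCOCc1ccncc1",                    # ether
    "c1ccccc1-c1ccncc1",               # biaryl
    "CCS(=O)(=O)NCc1ccccc1",           # sulfonamide
    "Cn1cccc1",                        # aromatic N - aliphatic C
    "CC(=O)Nc1ccc(cc1)C(=O)NC2CC2")    # two amides
}

the_fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_fixtures(seed = 42, n_actives_per_target = 40,
                              n_inactives = 80, n_background = 200)
    }
    cache
  }
})

fixture_fps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- the_fixtures()
      cache <<- list(
        actives = lapply(split(fx$compounds, fx$compounds$target),
                         function(df) morgan_fp(df$smiles, n_bits = 1024)),
        inactives = morgan_fp(fx$inactives$smiles, n_bits = 1024),
        background = morgan_fp(fx$background$smiles, n_bits = 1024))
    }
    cache
  }
})
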