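Package: mtlkit
Title: Multi-Target Ligand Design by Retrosynthetic Enumeration, Target
    Prediction and Docking-Score Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing multi-target ligands against protein
    combinations such as the adenosine A1/A2A receptors together with
    phosphodiesterase 10A. Known actives are fragmented at retrosynthetic
    (RECAP) bond types and recombined into a synthetically plausible
    candidate library, focused on heterocycles frequent across all targets.
    Candidates are gated by circular-fingerprint Bernoulli naive Bayes
    target prediction with enrichment statistics (empirical estimation
    score, Yates-corrected chi-square) and by docking-score thresholds
    calibrated to maximise F1 on labelled active/inactive score sets.
    Surviving series and compounds are profiled: ring-system and series
    frequencies, S/P-inclusive Ertl topological polar surface area,
    Lipinski and CNS rule filters, PAINS alerts, elemental composition,
    and Cheng-Prusoff Ki conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
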