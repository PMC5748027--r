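# mtlkit

Multi-target ligand design in R: retrosynthetic library enumeration,
ligand-based target prediction, docking-score gating, and physicochemical
profiling.

## The problem

A multi-target ligand is a single compound that engages a chosen set of
proteins — the motivating case here is the adenosine A1 and A2A receptors
together with phosphodiesterase 10A (PDE10A), a GPCR/enzyme triad whose
joint modulation of cAMP signalling is of interest in neurodegenerative
disease. `mtlkit` is for computational/medicinal chemists who want to
design such ligands from known single-target actives:

1. **Curate** per-target actives (Ki/IC50 ≤ 1 µM, confidence ≥ 8).
2. **Intersect** the top-30 ring systems of each target's chemotypes to
   find shared heterocycles (pyridine, pyrimidine, piperazine,
   1H-pyrazole in the packaged fixtures), with a whitelist mechanism for
   scaffolds characteristic of a target subset (e.g. 9H-purine).
3. **RECAP**: fragment actives at the 11 retrosynthetic bond types and
   recombine complementary fragments into a synthetically plausible
   candidate library, focused on the shared heterocycles.
4. **Predict**: per-target Bernoulli naive Bayes on 2048-bit circular
   (ECFP4-style) fingerprints; a candidate is a predicted multi-target
   ligand only if *every* target model calls it active. Enrichment of the
   library over a background pool is quantified by an empirical
   estimation score (resampling tail probability, cutoff 0.01) and a
   Yates-corrected chi-square (cutoff 0.05).
5. **Gate** on docking scores at per-target cutoffs calibrated by
   maximising F1 = 2PR/(P+R) on labelled active/inactive score sets
   (classification rule: active iff score ≤ t).
6. **Profile** survivors: substructural series frequencies,
   S/P-inclusive Ertl TPSA, Lipinski/CNS/PAINS filters, elemental
   composition, Cheng–Prusoff conversion Ki = IC50/(1 + C/K_D).

Docking itself is out of scope: scores are ingested from tables, and a
seeded Gaussian generator (`synth_scores()`) reproduces literature-scale
calibration conditions (81 actives vs 200 inactives; median pairs
−6.93/−5.64, −7.66/−6.01, −7.60/−5.66).

## Worked example

The packaged fixture `synthesized_compounds()` carries a 25-compound
4,6-disubstituted 2-aminopyridine-3-carbonitrile series encoded from
published IUPAC names. Profiling the furan-2-yl/4-methoxyphenyl analog
(compound 16):

```r
library(mtlkit)
syn <- synthesized_compounds()
cpd16 <- syn$smiles[syn$id == 16]

tpsa(cpd16)
#> [1] 85.07
```

85.07 Å² is the S/P-inclusive Ertl polar surface area — the number that
matters for the CNS-permeability rule (≤ 90 Å² primary band).

```r
elemental_percent(cpd16, from_smiles = TRUE)$mass_percent
#>     C     H     N     O
#> 70.09  4.50 14.42 10.98
```

These are the "analysis calculated" percents for C17H13N3O2 (MW 291.3).

```r
# IC50 3.2 uM in a competition assay with 1 nM radioligand, KD 0.7 nM:
cheng_prusoff(3200, C = 1, KD = 0.7)
#> [1] 1317.647      # Ki in nM: ~1.3 uM
```

Calibrating a docking gate on synthetic scores at the packaged PDE10A
medians and checking the compound's rule filters:

```r
sc <- synth_scores(seed = 1, target_id = "PDE10A")
best_f1_threshold(sc$score[sc$label == "active"],
                  sc$score[sc$label == "inactive"], "PDE10A")
#> <threshold_calibration> PDE10A: threshold -6.302, F1 0.6595
#>   (P 0.587, R 0.753); medians -6.856 / -5.712, Mann-Whitney p 5.75e-17

rule_filters(cpd16)[, c("lipinski_pass", "cns_pass", "pains_pass")]
#>   lipinski_pass cns_pass pains_pass
#> 1          TRUE     TRUE       TRUE
```

The calibrated cutoff (−6.30) falls between the active and inactive
medians, and the compound passes Lipinski, CNS and PAINS screens.

A full campaign on generated fixtures:

```r
fx <- make_fixtures(seed = 7)
cfg <- campaign_config(fixtures = fx, seed = 7, run_dir = "run")
man <- run_campaign(cfg)
man$counts
# curate -> scaffolds -> RECAP -> focus -> predict -> gate counts,
# with stage artifacts and manifest.json under run/
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/mtlkit.R` (`make-fixtures`, `run-all`, `profile`, `calibrate`).

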