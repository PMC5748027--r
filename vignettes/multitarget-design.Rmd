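---
title: "Designing multi-target ligands with mtlkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-target ligands with mtlkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlkit)
```

# The problem

A multi-target ligand binds a chosen combination of proteins at once — here
the motivating combination is the adenosine A1 and A2A receptors together
with phosphodiesterase 10A (PDE10A), a triad relevant to neurodegenerative
disease because all three converge on cAMP signalling. Designing such
ligands by hand is hard: the compound must sit in three different binding
sites and still be synthesizable. `mtlkit` implements a desk-scale pipeline
for this design problem:

1. **Curate** known actives per target (activity at most 1 µM, measurement
   confidence at least 8 on a 0–9 scale).
2. **Rank ring systems** per target and intersect the top 30 to find the
   heterocycles shared by all target chemotypes.
3. **Fragment** the actives at RECAP retrosynthetic bonds and **recombine**
   fragments into a synthetically plausible candidate library; **focus** it
   on the shared heterocycles.
4. **Predict** per-target activity with a Bernoulli naive Bayes model on
   circular fingerprints; call a candidate a predicted multi-target ligand
   only if every target model calls it active; quantify **enrichment** of
   the library against a background pool.
5. **Gate** candidates on docking scores at per-target cutoffs calibrated
   to maximise F1 on labelled active/inactive score sets.
6. **Profile** survivors: series frequencies, S/P-inclusive TPSA, logP,
   Lipinski/CNS/PAINS filters, elemental composition, Cheng–Prusoff Ki.

# Chemistry backend and graph model

All SMILES parsing, canonicalisation and SMARTS matching go through
OpenBabel (via `ChemmineOB`). Downstream algorithms operate on a light
molecular graph built from the *canonical* SMILES, so equal molecules give
equal graphs regardless of input spelling. Aromatic perception is
OpenBabel's default model; the kekulised bond orders of the canonical form
are used wherever explicit orders are needed, which keeps every derived
quantity deterministic.

Standardization (`standardize_smiles()`) keeps the largest covalent
fragment, then neutralizes simple charges: protonated N loses a proton when
it has one to lose and no negatively charged neighbour; `O-`/`S-`/`N-`
gain one under the mirror-image condition. Quaternary ammonium and
charge-separated groups written as adjacent opposite charges (nitro,
N-oxide) are deliberately left untouched — "neutralization" must not
invent chemistry. Tautomer handling is limited to the deterministic
canonical form of the backend (ruleset tag `ob-kekule-canonical-1` in the
output metadata); no tautomer enumeration is attempted, because differing
canonicalizers matter less than reproducibility.

# Ring systems

A ring system is what remains after deleting every acyclic bond:
fused/bridged/spiro assemblies stay whole, substituents fall away, and
heteroatoms double-bonded to a ring atom are retained. The retention rule
is what keeps xanthine — with its two exocyclic carbonyls — a single
framework rather than a naked purine skeleton; a naive smallest-ring split
would destroy exactly the vocabulary (xanthine, purine) that matters for
adenosine-receptor chemotypes. Frequency ranking counts molecules
containing a framework (not occurrences), and ties are broken
lexicographically so ranks are reproducible. The three-way intersection
keeps only heteroatom-containing frameworks; carbocycles such as benzene
are frequent everywhere and carry no target information. A whitelist lets
the user carry along frameworks characteristic of a subset of targets
(the packaged example: 9H-purine, characteristic of the adenosine
receptors only) — a config key, not a hard-coded special case.

# RECAP fragmentation and recombination

The eleven classical retrosynthetic bond types (amide, ester, amine, urea,
ether, olefin, quaternary N, aromatic N–aliphatic C, lactam N–aliphatic C,
biaryl, sulfonamide) are encoded as predicates on the molecular graph, with
the corresponding bond SMARTS carried in `recap_rules()` as documentation.
Matching is restricted to acyclic bonds (cutting ring bonds would produce
fragments that no one-step reaction reassembles). Every matching bond is
cut at once — equivalent to recursive cleavage, since cleavage cannot
create new cleavable bonds — and fragments below `min_heavy_atoms`
(default 3) are discarded; the default reflects that smaller fragments are
leaving groups rather than building blocks.

Recombination joins only *complementary* attachment points of the same rule
(acyl to amide-N, never acyl to acyl); the olefin and biaryl rules are
symmetric and rejoin either way. The olefin rule reforms a double bond, all
others a single bond. Unused attachment points are hydrogen-capped.
Products are re-canonicalised, deduplicated, and checked by re-parsing;
joins the backend rejects are counted, not silently lost. Candidates
identical to an input parent are flagged rather than dropped, so the
library size bookkeeping stays honest. When the full pairing table exceeds
`max_products`, a seed-determined uniform sample of pairs is enumerated —
full combinatorial runs at literature scale (hundreds of
thousands of products) are possible but pointless for testing.

# Target prediction

Fingerprints are circular (Morgan/ECFP4-style): initial atom invariants
(atomic number, heavy degree, H count, charge, ring and aromatic flags) are
iteratively hashed with sorted neighbour (bond, id) pairs to radius 2 and
folded modulo 2048 bits. Two conventions matter and are tested: an
environment that stops growing contributes no further features (methane has
exactly one environment), and environments covering identical bond sets are
counted once. Aromatic ring bonds hash with a dedicated bond code so the
kekulé assignment of the canonical form cannot leak into the bits.

The per-target classifier is Bernoulli naive Bayes with Laplace smoothing
(α = 1): every bit is an independent Bernoulli per class. Posteriors are
computed in log space and are reproducible from the stored tables. The
decision threshold is, by default, calibrated on the training actives as
the largest posterior cutoff retaining at least 99% recall — the
"high-confidence recall" reading of a recall-probability threshold of
0.01; the alternative reading (a plain posterior cutoff of 0.01) is
available as `threshold_mode = "fixed"`. A candidate is a predicted
multi-target ligand only if every configured target calls it active.

## Enrichment statistics

The estimation score asks: how often does a random background library of
the same size show a predicted-active rate at least as high as the
candidate library's? Background samples are drawn without replacement,
seeded, with sample size equal to the library size. Because hit rates are
discrete, the plain "at least as high" tail is conservative (super-uniform
under the null); the package therefore scores ties at half weight by
default (`tie_break = "midp"`), which restores null uniformity — verified
in the test suite by a Kolmogorov–Smirnov test over 200 null repeats at
1000 resamples. The conservative variant remains available
(`tie_break = "geq"`). A zero-hit-rate library reports an infinite average
ratio and is never called enriched; there is no division by zero. A target
is enriched when the estimation score is at most 0.01 and the
Yates-corrected chi-square p (library versus background 2×2 table) is at
most 0.05. The chi-square uses the closed-form continuity-corrected
statistic, clamped at zero when the correction overshoots, and errors on a
zero marginal naming the offending margin.

# Docking-score gate

Docking itself is out of scope — scores are ingested from tables, and a
synthetic Gaussian generator (`synth_scores()`) stands in for testing, with
per-target active/inactive median defaults of −6.93/−5.64 (PDE10A),
−7.66/−6.01 (A2AR) and −7.60/−5.66 (A1R) at 81 actives versus 200
inactives — the separation actually observed when validating docking
models for these targets. Calibration sweeps "active iff score ≤ t" over
all observed scores plus midpoints (the step-function F1 attains its
optimum on this grid by construction) and keeps the best-F1 threshold,
breaking ties toward the more permissive cutoff. Score–threshold
comparison is ≤; the boundary convention is configurable in spirit but
documented here once. Separation diagnostics report medians and a
Mann–Whitney test (exact for pooled n ≤ 20 without ties, normal
approximation with tie correction otherwise). The funnel report gives
per-stage counts and conditional fractions, and survivors are the
conjunction of the prediction call and all per-target score gates.

# Property profiling

TPSA is the Ertl fragment-contribution sum *including* the sulfur and
phosphorus terms. The published contribution table is encoded as a
mutually exclusive SMARTS set (connectivity, H count, valence, charge,
aromaticity and 3-ring membership pin each atom type exactly once), so the
value is a plain count-times-contribution sum; additivity over
disconnected fragments follows by construction. The S/P-inclusive dialect
is the one that reproduces the printed values for thiophene- and
thiazole-bearing compounds in the validation series (e.g. 90.9 Å² for the
thiophen-3-yl analog), which pins the reporting tool's convention.
logP and H-bond counts come from the OpenBabel descriptor
engine and are named in the report metadata; printed logP values from
other engines are recorded in the fixture for comparison but are not
reproduction targets — atom-contribution logP implementations disagree
far beyond rounding.

Lipinski's rule of 5 passes with at most one violation of MW ≤ 500,
logP ≤ 5, HBD ≤ 5, HBA ≤ 10. The CNS filter is necessarily this package's
own definition (no published threshold set exists for it): MW ≤ 450,
TPSA ≤ 90 with a documented borderline band to 120, logP ≤ 5, HBD ≤ 3,
all configurable. PAINS screening uses a curated subset (~15 SMARTS) of
the most common published alert families, re-expressed by hand, with
matched alert names reported; it is a subset, not the full ~480-alert
catalogue, and is documented as such. Elemental composition uses the
IUPAC 2021 conventional atomic weights, reported to two decimals;
Cheng–Prusoff is the exact formula Ki = IC50 / (1 + C/KD), which errors on
KD = 0 and degrades gracefully to Ki = IC50 at C = 0.

# The synthetic fixture generator

`make_fixtures()` emulates the *statistical structure* of a literature-scale input set
at desk scale, with defaults of 60 actives per target, 120 inactives and a
300-compound background pool (tests use smaller sizes; the packaged
defaults are the generator's notion of a realistic small campaign).
Per-target actives are planted heterocycle cores — pyridine, pyrimidine,
piperazine, 1H-pyrazole shared by all targets, purine and xanthine for the
adenosine receptors only — decorated with RECAP-joinable substituents;
core compositions are assigned by exact deterministic counts so tests can
demand exact recovery of the planted ranking. About 10% of activity
annotations are planted curation failures (value above 1 µM or confidence
below 8). Inactives and background come from non-core chemotypes, which
makes the naive Bayes classes separable by construction. What the
generator does *not* emulate: real chemotype diversity (a handful of
decorations versus thousands of scaffolds), assay noise structure,
activity cliffs, and any relationship between structure and docking score
(scores are independent Gaussians). Passing tests therefore demonstrate
correctness of the machinery, not predictive performance on real screens.

# Numerical choices and degenerate inputs

* Hashing uses a polynomial rolling hash modulo 2³¹−1, exact in double
  precision, so fingerprints are platform-independent.
* All random draws (recombination sampling, background resampling,
  synthetic scores, fixtures) take explicit integer seeds; callers' RNG
  state is saved and restored.
* The F1 sweep on an all-identical score set is flagged `degenerate`
  rather than failing.
* An empty required-framework set makes `focus_library()` the identity
  with a warning, so a failed intersection does not kill a campaign.
* Unparsable SMILES are skipped with the offending row numbers (file
  ingestion) or raised as errors naming the string (programmatic API).
* Problem sizes in the test suite (e.g. 40 actives per target, 200
  resampling repeats, 100 calibration seeds) were chosen as the smallest
  sizes at which the statistical properties under test are stable.

# Known limitations

* Docking is score ingestion only; no poses, no rescoring, and the
  published engine-specific thresholds reported for such campaigns are not
  reproducible here.
* Ligand-based predictions depend on the training actives; the packaged
  generator's separable classes make them look better than real screens
  would.
* The estimation score is an empirical tail probability — a documented
  stand-in for formulations whose details are unpublished, and
  reports carry a note saying so.
* Database-scale campaign numbers (extraction counts,
  six-figure library sizes, per-series percentages, prediction rates and
  docking cascade fractions) depend on specific database versions and
  commercial software and are out of reach at desk scale; the pipeline
  reproduces the *procedure*, and its printed physicochemical endpoints
  (TPSA, elemental analyses), exactly.
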