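---
title: "Methods: models, generators and design choices in oxyradapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators and design choices in oxyradapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyradapt)
```

`oxyradapt` reimplements, as a tested pipeline over synthetic data with known
ground truth, the computational analyses used to characterize convergent
adaptive mutations in the bacterial peroxide sensor OxyR: transcriptome
decomposition into i-modulons, structural proximity mapping of mutations,
allele screening of sequence collections, a proteome-allocation growth-cost
model, and lag-phase phenotyping. This vignette records the models, their
assumptions, the defaults that matter, and the design decisions taken where
the problem was genuinely open.

## The synthetic-data generators

Every downstream stage consumes only inputs the package can generate itself,
with the generating truth returned alongside. The generators emulate the
*statistical shape* of the real data, not its biology:

* **Expression** (`simulate_expression`): `X = S_true A_true + ε` on the log
  scale, with `ε ~ N(0, σ²)` i.i.d. Gaussian noise is the conventional model
  for log-TPM-like data; the default `σ = 0.25` is a realistic
  between-replicate spread for bacterial RNA-seq on the log2 scale. The
  default universe is 1,000 genes with planted modulons of 20–30 members
  mirroring the regulators the pipeline tracks (an OxyR-like group strongly
  elevated in evolved conditions, a LexA-like group responding in the
  growth-optimized strain, and a SoxS-like flat null group). Replicate
  columns of a condition share the same true activity; only noise differs.
  What the generator does *not* emulate: count overdispersion, library-size
  artifacts, batch structure, or correlated gene noise — so passing recovery
  tests demonstrate algorithmic correctness, not robustness to real RNA-seq
  pathologies.
* **Alleles** (`simulate_alleles` over `synthetic_oxyr_reference`): the
  reference is a 305-residue random protein with the functionally important
  OxyR positions pinned (C199, C208, R201, P99/103/107/111, T100, L113,
  H114, T129, A147, D172, L200, A213). The real *E. coli* OxyR sequence is a
  database object; the synthetic stand-in is labelled as such everywhere and
  preserves exactly what the screen logic needs — residue identities at the
  positions being screened. Codons are drawn uniformly per amino acid
  (genetic code table 11, no ambiguity codes), so codon-usage bias is
  deliberately absent. Background genomes are exact duplicates with
  probability `duplicate_rate`, otherwise carry 1–3 synonymous changes;
  planted genomes differ by exactly the requested nonsynonymous substitution
  plus the requested synonymous extras.
* **Structures** (`simulate_structure`): residue centers follow a 3.8 Å-step
  random walk (Cα–Cα-like spacing) with 1–5 heavy atoms jittered per
  residue; the second conformer applies exact per-residue rigid
  translations. All pairwise distances therefore follow in closed form,
  which is the point: the proximity stage is validated cell-by-cell against
  an exhaustive all-atom-pair oracle. No steric realism, secondary
  structure, or physics is intended.
* **Growth curves** (`simulate_growth_curves`): baseline OD until the
  dose-specific lag, then a logistic rise; a lag of `NA` marks a "no
  detectable growth" dose and produces a flat baseline. Defaults — baseline
  OD 0.02, carrying capacity 1.0, `μ_max = 0.8 h⁻¹`, one read per 10 min,
  OD noise SD 0.005, three replicates — are plate-reader-realistic for
  enteric bacteria in minimal medium. The lagged logistic is chosen because
  the downstream statistic needs only a well-defined lag, not mechanistic
  realism (no death phase, no peroxide decay kinetics).

All generators take an integer seed and are bitwise reproducible; seeds for
internal streams are derived from the governing seed so stages stay
independent yet jointly deterministic.

## Robust ICA and i-modulons

The decomposition treats genes as observations of sample-dimensional
signals. `center_to_reference` subtracts each gene's mean over the
reference-condition samples, so activities read as changes relative to the
wild-type baseline (reference bars sit at zero by construction). FastICA
(logcosh contrast, `α = 1`, symmetric decorrelation, tolerance `1e-8`, up to
500 iterations) runs from `n_restarts` random orthogonal rotations after
eigenvalue whitening in sample space.

Two numerical choices deserve a note:

* **Whitening without gene-mean removal.** The whitening step uses the
  second-moment matrix of the reference-centered data directly rather than
  column-centering it first. Centering would make every recovered weight
  vector mean-free over genes, while planted (and biological) regulon weight
  vectors are one-sided; keeping the mean component lets the least-squares
  projection `A = (SᵀS)⁻¹SᵀX` attain the rank-k optimum on the data as
  given, and recovery is scored on the same footing.
* **Sign and scale convention.** Columns of `S` are unit L2 norm with the
  largest-magnitude weight positive. This makes the decomposition unique up
  to component order and is what makes "same data, different seed"
  reproducibility testable.

Robustness clustering pools all components from all restarts, clusters them
by `1 − |r|` (complete linkage, cut at 0.2), and keeps clusters recurring in
at least `min_recurrence = 0.5` of restarts — conventional robust-ICA
practice. Fewer robust clusters than requested is a flagged outcome, not an
error; an all-zero input is flagged degenerate. Both the joint decomposition
and projection of new samples onto a fixed external `S`
(`project_activities`) are supported, since either convention is defensible
for scoring activities against a compendium-derived basis.

Membership uses `|weight| > k × 1.4826·MAD` with `k = 5`: conservative
enough that planted sets are recovered exactly at the default noise.
Regulator matching is the hypergeometric upper tail with Bonferroni
correction over the regulons tested. Differential activity is Welch's
two-sample t on replicate activities — bar-plus-replicates data without a
stated test convention; Welch is the safe default. The null control in the
test suite scores a flat-activity component by projection onto the known
weights, because a component with no variance is (correctly) not recoverable
by ICA after centering.

## Structure proximity and classification

Distances are minimum heavy-atom Euclidean distances between residue atom
sets — the stricter notion of proximity when no atom-subset convention is
given; Cα-only is available via `metric = "ca"`. PDB input keeps the first
chain, drops hydrogens, and resolves alternate locations to the
highest-occupancy copy. Missing residues yield flagged missing cells, never
an imputed number.

Classification is a pure rule function of the distance row. Region
membership decides first, in the order redox loop [199, 208] → flexible loop
[205, 216] → proline set {99, 103, 107, 111}. The redox loop is checked
before the flexible loop because positions 205–208 belong to both, and the
redox-loop mechanism (tetramerization of the reduced form) is the specific
one for the conserved Cys-208: a C208 mutation is read as destabilizing the
reduced tetramer, while a position like 213 — inside the flexible loop only
— is read as impairing the return of Cys-199 to the reduced conformation
and therefore favoring the oxidized form. Outside all regions, the nearest
annotated feature within `contact_cutoff = 8 Å` (a standard contact
distance; configurable) decides via its category; beyond the cutoff the
call is `ambiguous`. Dimer-interface (cross-chain) distances are out of
scope.

## Allele screening

Deduplication is exact string grouping at DNA and protein level after
trimming one terminal stop codon; ambiguity codes, frame problems and
internal stops are flagged and excluded rather than repaired. Alignment is
global Needleman–Wunsch under BLOSUM62 with gap open 11 / extend 1
(conventional protein-alignment defaults). Identity counts identical
aligned pairs over the alignment length; similarity counts positive-score
pairs — "similar" has no universal definition, so the scoring convention is
explicit and configurable. Substitutions are reported in reference
numbering; indels are reported separately and never matched against the
constitutive set.

The default matching rule is `position`: a genome is flagged for any
nonsynonymous change at a reference-set position. The exact-variant rule is
implemented too, but natural-isolate variants frequently differ from the
laboratory-observed residue at the same position (A213T beside observed
A213P/E, A147V beside A147E), so position matching is the rule that a
constitutive-activation screen needs. The default reference set contains
the laboratory-evolution positions plus the promoter-activity mutant
position 201 from the literature. Cross-species positions are mapped
through the alignment columns before structure lookup; positions aligned to
a gap return an explicit unaligned flag.

A note on scale: the real cross-species OxyR comparison requires the two
database protein sequences, and screening the public genome collections
requires their download. The package validates its alignment statistics on
constructed homologs with closed-form identity instead, and the screen's
worked example plants the isolate substitutions into a synthetic
collection. Deduplication counts of real collections are therefore not
reproduced here.

## The proteome-cost model

The model deliberately reduces proteome-constrained growth simulation to
the minimal linear allocation consistent with two scaling laws: growth
declines linearly as any single gene's expression rises
(`μ/μ0 = 1 − α·φᵢ·(f − 1)/Φ`, floored at 0 and capped at 1 unless
reallocation gains are enabled), and the slope `kᵢ = α·φᵢ/Φ` grows with the
gene's reference abundance. A single shared `α` across genes encodes the
assumption that slope variation is driven by reference abundance alone;
`fit_cost_model` recovers `α/Φ` by least squares through the origin on
points above the zero floor and refits per-gene slopes as a diagnostic —
genes whose individual slope deviates from the shared prediction by more
than `misfit_tol` raise a misfit flag instead of being silently averaged.
Regulon costs compose additively with ties broken by gene id. Absolute
growth rates, metabolic structure, and folding burden are out of scope.

## Lag-phase estimation

The tangent method fits sliding-window regressions to `log(OD)` versus time
and takes the time at which the maximum-slope tangent crosses the baseline
log-OD level — the conventional microbiological definition of lag. Three
defaults matter:

* **Baseline over the first 6 points** (median). With OD noise of 0.005 on
  a 0.02 baseline, a 3-point baseline propagates enough `log(baseline)`
  noise into the intercept that the estimate misses planted lags by more
  than a sampling interval; six points restore the margin while remaining
  well inside any realistic lag.
* **9-point windows**, restricted to stretches entirely above
  `baseline + delta` (`delta = 0.02` OD): near the baseline the log of the
  measurement noise dominates the slope, so tangents are only fit where the
  signal is clearly growing.
* **No-growth calls** use `delta_min = 0.05` OD of total rise; a no-growth
  curve has an undefined lag and propagates as an explicit flag ("missing
  bar"), never as a number.

The tangent estimator is exactly equivariant under time translation and
invariant under multiplicative OD rescaling (the window gate's OD threshold
scales with the data, as the tests exercise). Replicates are estimated
per curve and then summarized — never pooled into one fit — and each
strain's relative increases are referenced to its own mean zero-dose lag.
The threshold method (first crossing of `baseline + delta`) is provided as
a robustness check.

## Pipeline, determinism and problem sizes

`validate_config` fills defaults, rejects unknown keys and type errors;
`run_pipeline` executes simulate → ica / proximity / scan / cost / lag,
writing TSV/JSON artifacts and a manifest with an MD5 hash per output. One
seed governs all stages; two runs under the same seed are hash-identical.

The test and acceptance suites run at deliberately compact sizes chosen to
exercise every code path with comfortable statistical margins: 300-gene
universes with 12 samples for the ICA recovery and power simulations (200
replicate simulations for power and null calibration), 220-residue
structures for the exhaustive distance oracle (240 matrix cells), 57-genome
collections for the screen, 100 random models for the abundance-slope law,
and 100 seeded curves for lag recovery. These sizes are the package's
choices for fast, deterministic verification; all functions accept larger
inputs unchanged.

## Known limitations

* The ICA stage does not choose the component count automatically; it
  reports a flagged shorter model when fewer robust clusters exist.
* The structure stage interprets single chains; tetramer- and
  dimer-interface geometry is out of scope, so classifications lean on
  sequence regions plus single-chain distances.
* The cost model is linear by construction and cannot capture saturation or
  regulatory feedback; it prices expression, not benefit.
* The allele screen calls substitutions only; genomes whose OxyR differs by
  indels are reported but never matched against the constitutive set.
* Synthetic generators trade realism for exactness, as detailed above; real
  datasets will stress assumptions (noise structure, disordered residues,
  codon bias, plate-reader drift) that the generators intentionally omit.
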