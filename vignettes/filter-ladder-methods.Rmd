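---
title: "Methods: the spectral-count filter ladder, NSAF categorisation, and variability statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the spectral-count filter ladder, NSAF categorisation, and variability statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scladder)
```

## The problem

Label-free spectral counting infers relative protein abundance from the
number of MS/MS spectra matched to each protein in a run. It is cheap and
broadly applicable, but noisy: identifications fluctuate between technical
replicates, common contaminants (keratins, albumin, immunoglobulins)
pollute every list, and low-count proteins have large relative counting
error. When several datasets — different tissue states, different
sample-preparation protocols, unequal numbers of samples and replicates —
must be compared, raw identification lists are not comparable at all.

`scladder` addresses this with a fixed, fully specified preprocessing
ladder that reduces each dataset to the proteins that are *reliably*
identified and *reliably* quantified, so that downstream comparisons
(set overlap, variability, protocol differences) operate on lists of
equivalent stringency. The motivating application is the chorionic villus
(placental) proteome, a tissue studied for low-abundance and
previously undetected ("missing") proteins, but nothing in the code is
placenta-specific: the annotation table defines which accessions count as
"tissue-relevant".

## The filter ladder

Runs are addressed by `dataset_sample_replicate` keys against a declared
design (`study_design()`; `chorionic_design()` is the built-in
six-dataset registry: 3 elective-state and 3 missed-state datasets, 2–3
technical replicates per sample, 20 runs).

Per dataset the six stages are, each applied to the previous stage's
survivors:

1. **`p_total()`** — the union of accessions over the dataset's runs.
2. **`p_placenta()`** — removes accessions whose contaminant
   identification frequency (fraction of negative-control experiments in
   which the protein appears, a CRAPome-style table) is ≥ 0.67; removes
   P01834 and P02768 unconditionally (immunoglobulin kappa constant and
   serum albumin, ubiquitous in clinical material regardless of
   frequency); keeps only accessions with a known placental transcript.
   The contaminant and annotation restrictions are pure set operations, so
   their order is immaterial.
3. **`i_successful()`** — the two-peptide rule at high confidence: ≥ 2
   distinct peptide *sequences*, each with confidence ≥ 99 on the 0–100
   integrator scale, in at least one run. Distinct sequences, not
   spectra: observing one peptide twice is one piece of sequence evidence.
   The score threshold is read as per-peptide; a protein-level reading is
   possible but the per-peptide rule is the standard interpretation of
   "two confident peptides" and is what the package implements.
4. **`i_proteins()`** — within-sample reproducibility: ≥ 2 distinct
   peptides (any score) in the required fraction of a sample's
   replicates, in at least one sample. "Two thirds or more" of *k*
   replicates is generalised as ⌈2k/3⌉ (so 2 of 3); 2-replicate samples
   use the ALL rule. By default the rule is derived from the design
   (ALL for 2 replicates, TWO_THIRDS for 3+) and can be overridden per
   dataset in `ladder_rules()`.
5. **`i_reliably()`** — the same logic across samples: ALL samples for
   single-sample datasets, ⌈2m/3⌉ of *m* samples for multi-sample ones.
   For a single-sample dataset this stage is the identity on stage 4,
   which is why multi-replicate single-sample designs show identical
   `i_proteins`/`i_reliably` counts.
6. **`q_reliably()`** — quantification reliability on NSAF values pooled
   over all of the dataset's runs: coefficient of variation ≤ 0.16 *or*
   fold change (max/min) ≤ 1.25. The disjunction is deliberate and easy
   to misread as a conjunction: a protein with a modest CV *or* a tight
   range passes. CV uses the sample standard deviation (n − 1), matching
   R's `sd()`. Proteins quantified in fewer than two runs are excluded
   (CV/FC undefined) and counted in a message. For multi-sample datasets
   the per-run values are pooled rather than aggregated per sample first;
   pooling is the stricter and simpler convention.

The stages form a descending chain
`P_total ⊇ P_placenta ⊇ I_successful ⊇ I_proteins ⊇ I_reliably ⊇ Q_reliably`,
which the test suite asserts on every simulated study, and each stage is
checked against an independently coded brute-force set comprehension on
randomized small studies.

`summarize_counts()` reports cross-dataset `mean ± SD` (sample SD, both
rounded half-away-from-zero to integers), the convention used for the
published per-dataset counts bundled in `reference_ladder_counts()`.

## NSAF, centering, and abundance categories

`nsaf()` computes `NSAF_i = (SpC_i/L_i) / Σ_j (SpC_j/L_j)` per run;
values are non-negative and sum to 1 over the run's quantified proteins.
Zero-count proteins are flagged unquantified rather than entered as NSAF
0 — a 0 would make the fold change undefined and would conflate "absent
in this run" with "present at the detection floor".

For categorisation, each protein's *mean* NSAF across the dataset's runs
is taken (one number per protein), the per-dataset vector is mean-centred
(so the centred values sum to 0), and proteins are ranked ascending. The
bottom `floor(n/4)` are LOW, the top `floor(n/4)` HIGH, the remainder
MEDIUM. Rank-based quartiles (rather than interpolated quantile values)
make the category sizes exact and deterministic; ties are broken by
accession so results do not depend on input order. The centred-NSAF
values at the LOW/HIGH boundaries are the dataset's thresholds, and
`threshold_summary()` reports their cross-dataset `mean ± SD` to three
decimals. `low_abundance_crosscheck()` intersects the LOW category with a
user-supplied external low-expression list and reports per-protein
dataset provenance (`"1, 6"`).

## Variability, trees, entanglement, and the protocol comparison

Per-run protein lists at a ladder stage are compared with the Jaccard
distance `1 − |A∩B|/|A∪B|` — the natural choice for presence/absence
lists, and pluggable in principle since everything downstream consumes a
distance matrix. For the confident-identification stage, a run's list is
the dataset's `P_placenta` survivors meeting the two-confident-peptide
rule *in that run*; for the quantification stage it is the dataset's
`Q_reliably` set restricted to proteins quantified in that run.

`cluster_runs()` wraps `stats::hclust` with complete linkage by default
(the `hclust` default; average and single are available — the linkage
used for the original analyses is not documented, so the package exposes
the choice). `design_reference_tree()` builds the "manually set" side of
a tanglegram: an ultrametric tree in which runs join their sample, then
their dataset, then their protocol.

`entanglement()` quantifies leaf-order disagreement: with each tree's
leaf order, `Σ |rank_left(i) − rank_right(i)|^L`, normalised by the value
of that sum for an exactly reversed order, giving \[0, 1\] (0 = aligned).
`L = 1.5` follows the convention of tanglegram software. No leaf-order
optimisation is applied before measuring — the point is to compare the
clustering against the declared design order as-is — but
`align_dendrogram()` offers a rotation-only reordering for users who want
the aligned view.

`rank_sum_exact()` implements the Wilcoxon rank-sum (Mann–Whitney) test
with the U-statistic convention and mid-ranks for ties. For groups of up
to 12 it enumerates all `choose(n1+n2, n1)` assignments and doubles the
smaller tail (capped at 1); beyond that it falls back to the normal
approximation with a tie correction and says so. The exact two-sided
critical value at sizes 6 and 6 is W = 5, which is the regime of
`protocol_variability_comparison()`: two 3-replicate datasets per
protocol group give `2 × choose(3,2) = 6` within-dataset replicate-pair
distances per group.

## The synthetic-data generator

`simulate_study()` emulates the statistical structure of post-search
reports so every downstream stage can be tested against known ground
truth:

* protein lengths are log-normal (default median 400 aa, σ_log 0.55,
  floored at 50 aa);
* each protein carries an abundance class (LOW/MEDIUM/HIGH with weights
  0.25/0.5/0.25 and relative expression 1/4/16 — quartile-like class
  sizes with well-ordered means);
* per-run spectral counts are negative binomial with mean
  `base_count × class × length/400` times a per-replicate log-normal
  stability factor (σ_log `cv_target_stable` = 0.08 for stable proteins,
  `cv_target_unstable` = 0.8 for unstable ones; 60% stable by default) —
  spectral counts are overdispersed in practice, and the stability factor
  is the knob the CV/FC filter responds to;
* detected proteins receive 1–15 peptide evidences (roughly √count),
  scored near 99.6 when backed by ≥ 2 spectra and near 70 for
  single-spectrum detections, on the 0–100 scale;
* 5% of proteins are contaminants whose frequencies are drawn in two
  clusters straddling the 0.67 cutoff, so the exclusion boundary is
  exercised from both sides; 95% of the rest carry placental annotation.

The defaults describe a moderate-depth study (`base_count = 12`) in which
counting noise is visible, so the ladder's attrition is qualitatively
realistic: a large fraction of identified proteins fails the CV/FC
filter, as it does on real reports.

`sim_params_well_separated()` is the documented setting for ground-truth
recovery checks. The CV of a stable protein's NSAF is approximately
`sqrt(1/μ + 1/size + σ_log²)` (counting + overdispersion + replicate
factor), so for *every* stable protein — including the shortest (50 aa)
LOW-class one, whose expected count is `base_count/8` — to sit safely
inside the CV ≤ 0.16 region, the setting uses `base_count = 800`,
`size = 400`, `σ_log = 0.04`, giving a worst-case stable CV ≈ 0.12.
Unstable proteins (σ_log 0.8) fail both CV and FC except by chance; the
main chance channel is the fold change over 2-replicate datasets, which
caps attainable precision near 0.95 there and is visible in the
acceptance numbers.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: dataset-specific protein complements (every
protein exists in every dataset, so clustering of per-run lists does not
recover the design hierarchy and the design-vs-clustering entanglement is
far above the near-zero values real protocol-structured data produce);
peptide sequences are arbitrary 7–30 aa strings, not tryptic digests, so
nothing peptide-chemical can be inferred; no run-order, batch, or
chromatography drift; contaminant abundance behaves like any other
protein's.

## Numerical and interface choices

* Reports are TSV with a header; multi-accession peptide cells are
  semicolon-separated (the common integrator export convention). Scores
  outside \[0, 100\], non-integer lengths/counts, duplicate accessions and
  malformed keys are rejected with classed conditions
  (`scladder_validation_error`, `_format_`, `_structural_`, `_io_`),
  which the command-line driver maps to distinct exit codes.
* Accessions missing from the annotation table are treated as lacking
  transcript evidence (conservative toward the tissue filter) and
  counted in a message.
* The run-level QC threshold (`qc_runs()`) is a required configuration
  value, not a constant: the spectral-quality cutoff is data-derived
  (e.g. a low quantile of the observed per-run spectrum counts), and
  whether "spectra" means acquired or matched spectra depends on the
  upstream tooling — both work, since the threshold applies to whatever
  count the report carries.
* `simulate_study()` seeds the RNG locally and restores the caller's
  RNG state, so simulations are reproducible without side effects.
* The pipeline (`run_pipeline()`) validates its configuration before any
  computation and writes outputs through a staging directory, so a
  failing stage leaves no partial results.

## Problem sizes used by the test suite

Unit tests use constructed studies of ≤ 5 proteins with hand-computed
expectations. Oracle-equivalence runs 100 randomized studies of 20–50
proteins against the brute-force set comprehension; invariant sweeps use
20 seeds at 80 proteins on the full 20-run design; ground-truth recovery
uses 500 proteins under the well-separated setting. The exact rank-sum
test is verified against `stats::wilcox.test`'s exact distribution for
all group sizes up to 6 × 6.

## Known limitations

* Protein inference is upstream: reports are taken as already grouped,
  and shared peptides count toward every accession they list.
* The ladder's thresholds (2 peptides, score 99, frequency 0.67, CV
  0.16, FC 1.25) are conventions of the motivating workflow, exposed in
  `ladder_rules()` but not auto-tuned.
* Quartile thresholds are reported on centred mean-NSAF values; they are
  comparable across datasets only to the extent that list sizes are.
* The exact rank-sum enumeration is combinatorial; beyond 12 per group
  the normal approximation is used.
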