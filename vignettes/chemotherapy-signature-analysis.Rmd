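---
title: "Mutational signature analysis of paired pre/post-chemotherapy tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational signature analysis of paired pre/post-chemotherapy tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platsig)
```

## The problem

When a tumor is sampled before and after a course of DNA-damaging
chemotherapy, the mutations private to the post-treatment sample carry the
footprint of the drug (mixed with spatial sampling effects). `platsig`
implements the analysis chain needed to isolate and characterize such a
footprint from somatic SNV tables alone: trinucleotide-context catalogs,
de-novo signature discovery by NMF, fixed-signature activity refitting,
cross-genome signature renormalization with permutation-based significance,
transcriptional strand-bias tests, clonality-weighted signature
attribution, and intratumoral-heterogeneity covariates.

Because matched pre/post patient cohorts are controlled-access data, the
package ships a first-class synthetic cohort generator that plants every
structure the chain is meant to detect; all tests and the reproduction
script run against it.

## Catalogs and the pyrimidine convention

Each SNV is represented by its substitution and the two reference-strand
flanking bases. Substitutions from a purine are reverse-complemented
(alleles and flanks, flanks swapped), leaving 6 substitution classes x 16
contexts = 96 channels. Channels are ordered class-major (C>A, C>G, C>T,
T>A, T>C, T>G; flanks A,C,G,T), the ordering of published signature
tables, so external reference panels align by construction. The stranded
catalog splits each channel into coding(+)/noncoding(-) sub-channels,
where "coding" means the pyrimidine-centered representation lies on the
untranscribed strand; the convention is fixed in `stranded_channel()`.

Records whose stated reference allele disagrees with the reference
sequence, records at contig edges, and records with ambiguity codes in
the context are excluded and counted in a QC attribute rather than
silently dropped.

## Discovery, refitting and the two error traces

Discovery factorizes the channels-by-samples count matrix $V \approx WH$
with the KL-divergence multiplicative updates. The factorization is
non-convex, so `discover_signatures()` performs `n_runs` (default 200)
independently seeded runs and keeps the run with the minimum Frobenius
residual $\lVert V - WH \rVert_F$; `rank_survey()` reports cophenetic
coefficients (consensus of dominant-signature co-clustering across runs,
average linkage), residuals and residual sums of squares over a rank
range, and deliberately does not automate the rank choice.

Two error traces are returned for every run. The KL objective is the
quantity the updates provably never increase, and the monotonicity
contracts in the test suite are asserted on it. The Frobenius residual is
the quantity used for run selection and for refit termination; under KL
updates it is non-increasing only to first order and oscillates at
relative magnitude around $10^{-5}$ on the plateau, which is exactly why
the refit stopping rule watches a windowed average slope rather than
per-iteration decrease.

`infer_activities()` holds $W$ fixed and iterates only the $H$ update from
a random scale-appropriate start ($H_0$ entries uniform, scaled to the
sample totals). Iteration stops when
$(\mathrm{err}_{i-w} - \mathrm{err}_i)/w < \tau$ with window $w = 20$
iterations and $\tau = 10^{-4}$ (both exposed in `refit_config()`), or at
a hard cap of 10,000 iterations, which exists only to guard degenerate
tolerance settings. For a single signature the fixed point is the sample
total, a closed form the tests check to 0.1%. A pseudocount of $10^{-12}$
in update denominators keeps all-zero channels and samples well-defined;
an all-zero sample simply receives zero activity.

## Renormalization, substitution, and permutation nulls

A signature measured in one territory maps to another by scaling each
channel by the target/source frequency ratio of its trinucleotide context
(32 pyrimidine-collapsed contexts applied uniformly to the 3 channels
each) and renormalizing; the map is exactly invertible for strictly
positive tables, and a zero source frequency under nonzero signature mass
is an error, never a silent drop.

To ask whether a discovered candidate signature describes the same
process as an external spectrum, the candidate's column is replaced by
the spectrum, activities are re-inferred, and the two activity vectors are
correlated across samples (Pearson). Significance is empirical: surrogate
replacements are drawn either by permuting all 96 channel entries jointly
(the literal reading; permutation within substitution classes would be a
stricter null and is not implemented) or as $w \cdot \mathrm{ref}_a +
(1 - w)\cdot \mathrm{ref}_b$ with a uniformly chosen signature pair and
$w \sim U(0,1)$. The empirical p-value is the proportion of null
correlations at least as large as the observed one, with denominator $n$
and no add-one correction — matching the proportion-based definition the
method is built around. A calibration property is tested: when the
observed spectrum is itself a null draw, the empirical p-value is
approximately uniform.

## Strand bias and clonality-weighted attribution

Per substitution class, coding-strand counts are tested against
Binomial(total, 1/2), two-sided by doubling the smaller exact tail
(capped at 1) since no direction is pre-specified. Tests are run both on
raw class totals and on counts attributed to each signature; attributed
counts are real-valued credit sums rounded to integers for the test. No
multiple-testing correction is applied across the six classes in the
primary columns, matching per-class reporting conventions, but a
Benjamini-Hochberg column is emitted alongside.

A mutation in channel $c$ of a tumor with activities $h$ credits signature
$k$ with $h_k W_{ck} / \sum_j h_j W_{cj}$. Credits pool into clonal and
subclonal mass per signature (clonal = subclone CCF equal to 1 within
$10^{-3}$), pooled across samples cohort-wide, and homogeneity of the
subclonal proportion is tested with a Pearson chi-squared on the
$K \times 2$ credit table with $K - 1$ degrees of freedom. The credits
are real-valued but treated as counts, a documented caveat of the
approach itself. Mutations with unknown clonality or zero signature mass
on their channel are excluded and counted.

## Heterogeneity metrics

Per tumor, heterogeneity is the proportion of labeled mutations that are
subclonal; per patient, the number of subclones with positive CCF in
either tumor (a subclone present in both counts once). High/low flags use
strict-greater cutoffs at 0.2 and 6 respectively — boundary inclusion is
not canonical, so both the continuous values and the flags are emitted
and the cutoffs are arguments. Survival modeling itself is out of scope:
the package emits the covariate table (with clinical pass-through
columns) for external survival tooling.

Paired load comparisons restrict to sites detected, or powered for
detection, in both tumors. Detection power is
$P(\mathrm{alt} \ge 3)$ under Binomial(depth, expected VAF) — the
supporting-read filter reused as the detection bound, with the expected
VAF supplied by the caller (purity x CCF / 2 for a heterozygous diploid
site). The exact power model behind the original 80% rule is not
published; this binomial substitute is deliberate, documented, and
configurable in `power_model()`.

## What the synthetic cohorts emulate — and what they do not

`simulation_config()` defaults encode the study-scale conditions: 30
patients, 2,000 mutations per tumor, three background signatures with
per-patient Dirichlet(1) exposures, and a treatment signature confined to
post-private subclonal mutations at a 15% cohort-mean burden. Choices the
defaults make, with reasons:

* **Per-patient treatment burden** is Uniform(0.05, 0.25) rather than a
  fixed 15% per patient. Treatment-signature activity varies widely
  between tumors, and a constant share is degenerate for factorization (a
  constant-proportion signature is collinear with the mean background).
* **Subclone structure**: a clonal trunk (CCF 1/1) carrying most shared
  mutations, one shared subclonal population, and one private subclone
  per side; shared subclonal mutations are rare, as observed in paired
  designs. Subclonal CCFs are Uniform(0.15, 0.7).
* **Detection**: depths are negative binomial (mean 150, dispersion 5,
  typical exome coverage), purities Uniform(0.5, 0.9), alt reads binomial
  at VAF = purity x CCF / 2, detection at 3 supporting reads. Emitted
  tables contain only detected mutations, so the power filter is
  genuinely exercised.
* **Strand bias**: noncoding:coding = 3 for the treatment signature in
  C>A, C>T, T>A and T>C (the transcription-coupled-repair pattern
  expected of platinum adducts), 1 elsewhere; 80% of mutations get a
  strand assignment.
* **Channels** are drawn i.i.d. from the subclone's signature mixture —
  the multinomial model implicit in signature analysis.

Not emulated: real genomic coordinates and hotspot structure, copy-number
variation and multiplicity, CCF estimation error (an optional beta-noise
switch exists, default off), sequencing artifacts, and indels. Passing
tests therefore demonstrate correctness of the chain under the
multinomial signature model and power-limited detection — not robustness
to mis-estimated CCFs or copy number.

## Numerical and design choices

* Discovery initialization: run $r$ uses seed `base_seed + r - 1`;
  $W_0$ columns uniform-normalized, $H_0$ uniform scaled to the catalog
  mass. All randomness in the package flows through explicit seeds.
* Discovery stops at 2,000 iterations or a relative residual change below
  $10^{-6}$.
* Factor scale convention: $W$ columns renormalized to sum 1 with
  compensating row scale on $H$, leaving $WH$ unchanged.
* Cosine matching threshold 0.85; ties broken toward the lower reference
  index and flagged. Similarity to the mean of named reference pairs is
  reported on request, since some processes are described by a pair of
  published signatures.
* Problem sizes in the test suite and reproduction script (cohorts of
  2-30 patients, 100-200 NMF runs, permutation nulls of 200-1,000 draws,
  calibration at 200 replicates) were chosen as the smallest sizes at
  which the planted structure is comfortably identifiable.

## Known limitations

* The chi-squared enrichment test treats fractional credits as counts;
  with few attributed mutations its p-values are approximate.
* The two-sided binomial test is conservative at small totals
  (discreteness), so its realized type-I error sits slightly below the
  nominal level.
* Channel permutation nulls are exchangeable over all 96 channels; a
  within-class permutation null would be stricter for signatures with
  strong class structure.
* Genes transcribed on both strands are not modeled; strand assignment
  is taken from the input annotation as given.

## A five-minute worked run

```{r, eval = FALSE}
cfg <- simulation_config(n_patients = 8, mutations_per_tumor = 1000,
                         seed = 1)
cohort <- generate_paired_cohort(cfg)
post_only <- extract_post_only(cohort$pre, cohort$post, cohort$sites)
disc <- discover_signatures(build_catalog(post_only), rank = 3,
                            n_runs = 50, seed = 1)
match_signatures(disc$signatures, cohort$truth$signatures)
```

The numbered scripts under `analysis/` run the same chain at the default
cohort scale and write every table under `results/`.
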