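# platsig

Mutational signature analysis for matched pre-/post-chemotherapy tumor
pairs.

When the same tumor is sequenced before and after DNA-damaging
chemotherapy, mutations private to the post-treatment sample are enriched
for the drug's mutational footprint. `platsig` is for analysts who want to
isolate and characterize such a footprint from somatic SNV tables: it
builds trinucleotide-context catalogs, discovers signatures de novo,
refits fixed signature sets, tests candidate spectra against external
ones with permutation nulls, tests transcriptional strand bias, attributes
per-mutation credit by clonality, and computes intratumoral-heterogeneity
covariates. Real paired cohorts are controlled-access, so the package
includes a seeded synthetic cohort generator that plants every structure
the chain detects; the whole pipeline is testable offline.

## The model

Each SNV is one of 96 channels: 6 pyrimidine-reference substitution
classes (C>A, C>G, C>T, T>A, T>C, T>G) times 16 flanking-base contexts,
purine-reference mutations reverse-complemented. A cohort is a count
matrix `V` (channels x samples), factorized as

    V ≈ W H,   W ≥ 0 (channels x K, columns sum to 1),  H ≥ 0 (K x samples)

by KL-divergence multiplicative updates; 200 seeded runs are performed and
the run with minimum Frobenius residual ‖V − WH‖ is kept. With `W` fixed,
activities `H` are re-inferred by iterating only the H-update until the
windowed slope of the residual falls below 1e-4 over 20 iterations.
Downstream statistics: cosine matching to reference panels at 0.85;
context-frequency renormalization of spectra between territories;
Pearson correlation of activities after substituting a candidate
signature with an external spectrum, with empirical p-values from channel
permutations and random reference-pair combinations; exact two-sided
binomial tests of coding/noncoding asymmetry per class; per-mutation
credit `h_k W[c,k] / Σ_j h_j W[c,j]` pooled by clonality with a
chi-squared test (df = K − 1); and paired load comparisons restricted to
sites with detection power ≥ 0.8 under a Binomial(depth, VAF) model
requiring 3 supporting reads.

## Worked example

The numbered drivers under `analysis/` run the full chain on the default
synthetic cohort (30 patients, 2,000 mutations per tumor, three background
signatures plus a post-only subclonal treatment signature at a 15%
cohort-mean burden):

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_catalogs.R
Rscript analysis/03_discover.R 1
Rscript analysis/04_refit_compare.R 1
Rscript analysis/05_strand_bias.R 1
Rscript analysis/06_attribution_heterogeneity.R 1
```

Signature discovery on the mutations private to post-treatment tumors
recovers the planted treatment signature:

```
post-only signatures matched to planted truth:
  signature best_match cosine matched label   tie
1        S1        BG3  0.900    TRUE   BG3 FALSE
2        S2        BG2  0.936    TRUE   BG2 FALSE
3        S3        TRT  0.995    TRUE   TRT FALSE
```

Refitting the post-treatment catalog with the recovered signature puts its
cohort activity at the planted burden, and substituting the planted
spectrum for the recovered candidate leaves the inferred activities
essentially unchanged — far beyond what either null allows:

```
cohort activity fractions: BG1=22.3%, BG2=30.2%, BG3=31.7%, TRT=15.8%
substitution Pearson r (candidate vs planted spectrum): 0.999
null 'permute_channels': observed r 0.999, empirical p 0.0000 (n = 1000)
null 'reference_combination': observed r 0.999, empirical p 0.0000 (n = 1000)
```

The injected transcription-strand asymmetry is flagged in exactly the four
biased classes (coding-strand depletion in C>A, C>T, T>A, T>C), and the
treatment signature — planted only in post-private subclones — shows
roughly double the cohort's subclonal fraction:

```
classes with p < 0.05 for the treatment signature: C>A, C>T, T>A, T>C
subclonal fractions: BG1=25%, BG2=25%, BG3=24%, TRT=49%
overall subclonal fraction: 28%
subclonal enrichment: chi-squared 2364.5, df 3, p 0
paired load change: mean -0.2 mutations, t-test p = 0.987
```

The vignette (`vignettes/chemotherapy-signature-analysis.Rmd`) documents
the model, the stopping rules, the generator's assumptions and the known
limitations.

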