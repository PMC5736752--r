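#!/usr/bin/env Rscript
# Stage 6: clonality-weighted signature attribution with the subclonal
# enrichment test, per-patient heterogeneity covariates, and the paired
# pre/post load comparison under the detection-power filter.

library(platsig)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1

post <- read_mutations("results/cohort_post.tsv")
pre <- read_mutations("results/cohort_pre.tsv")
truth <- read_signatures("results/truth_signatures.tsv")
H <- read_catalog("results/activities_post.tsv")
subclones <- read.table("results/truth_subclones.tsv", header = TRUE,
                        sep = "\t")
cls <- read.table("results/site_classification.tsv", header = TRUE,
                  sep = "\t")

post_ch <- mutation_channels(post)
tab <- aggregate_attributions(post_ch, truth, H)
write.table(tab, "results/attribution_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
chi <- subclonal_enrichment_test(tab)
cat(sprintf("subclonal fractions: %s\n",
            paste(tab$signature, sprintf("%.0f%%", 100 * tab$subclonal_fraction),
                  sep = "=", collapse = ", ")))
cat(sprintf("overall subclonal fraction: %.0f%%\n",
            100 * attr(tab, "overall_subclonal_fraction")))
cat(sprintf("subclonal enrichment: chi-squared %.1f, df %d, p %.3g\n",
            chi$statistic, chi$df, chi$p_value))
jsonlite::write_json(list(statistic = chi$statistic, df = chi$df,
                          p_value = chi$p_value),
                     "results/subclonal_enrichment.json", auto_unbox = TRUE,
                     digits = NA)

met <- heterogeneity_metrics(pre, post, subclones)
write.table(met, "results/heterogeneity_covariates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("mean subclonal proportion pre %.2f, post %.2f; mean subclones %.1f\n",
            mean(met$prop_subclonal_pre), mean(met$prop_subclonal_post),
            mean(met$n_subclones)))

powered <- cls[cls$timing != "unpowered", ]
pre_counts <- vapply(met$patient, function(p) {
  sum(powered$patient == p & powered$timing %in% c("shared", "pre_only"))
}, numeric(1))
post_counts <- vapply(met$patient, function(p) {
  sum(powered$patient == p & powered$timing %in% c("shared", "post_only"))
}, numeric(1))
shared_counts <- vapply(met$patient, function(p) {
  sum(powered$patient == p & powered$timing == "shared")
}, numeric(1))
loads <- compare_loads(pre_counts, post_counts, shared_counts)
cat(sprintf("paired load change: mean %+.1f mutations, t-test p = %.3f\n",
            loads$mean_change, loads$t_p))
jsonlite::write_json(loads, "results/load_comparison.json",
                     auto_unbox = TRUE, digits = NA)
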