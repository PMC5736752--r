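#!/usr/bin/env Rscript
# Stage 1: simulate the paired pre/post cohort the rest of the analysis
# consumes. Defaults encode the study conditions: 30 patients, 2000
# mutations per tumor, 3 background signatures, a post-only subclonal
# treatment signature at a 15% cohort-mean burden.

library(platsig)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1

dir.create("results", showWarnings = FALSE)
cfg <- simulation_config(seed = seed)
cohort <- generate_paired_cohort(cfg)

write.table(cohort$pre, "results/cohort_pre.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cohort$post, "results/cohort_post.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cohort$sites, "results/cohort_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_signatures(cohort$truth$signatures, "results/truth_signatures.tsv")
write.table(cohort$truth$subclones, "results/truth_subclones.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS_path <- NULL  # truth mutations kept as TSV for transparency
write.table(cohort$truth$mutations, "results/truth_mutations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d patients; %d detected pre, %d detected post mutations\n",
            cfg$n_patients, nrow(cohort$pre), nrow(cohort$post)))
cat(sprintf("treatment signature planted in %d post-only subclonal mutations\n",
            sum(cohort$truth$mutations$signature == "TRT")))
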