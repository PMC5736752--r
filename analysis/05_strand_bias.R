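#!/usr/bin/env Rscript
# Stage 5: transcriptional strand bias. The 192-channel post-treatment
# catalog is tested per substitution class, both on raw class totals and
# on counts attributed to each signature.

library(platsig)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1

V192 <- read_catalog("results/catalog_post_192.tsv")
truth <- read_signatures("results/truth_signatures.tsv")
W192 <- matrix(rep(truth, each = 2) / 2, 192, ncol(truth),
               dimnames = list(channel_labels_192(), colnames(truth)))

fit <- infer_activities(collapse_stranded(V192), truth,
                        refit_config(seed = seed))
tab <- stranded_signature_bias(W192, fit$activities, V192)
write.table(tab, "results/strand_bias.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("treatment-signature strand asymmetry by class:\n")
print(tab[tab$signature == "TRT", ], digits = 3, row.names = FALSE)
flagged <- tab[!is.na(tab$p_value) & tab$p_value < 0.05 &
                 tab$signature == "TRT", "snv_class"]
cat(sprintf("classes with p < 0.05 for the treatment signature: %s\n",
            paste(flagged, collapse = ", ")))
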