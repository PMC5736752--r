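#' Exact binomial test for transcriptional strand asymmetry
#'
#' Under no transcription-coupled repair, a mutation class should fall on
#' the coding and noncoding strands with equal probability; this tests
#' coding counts against Binomial(total, 0.5). The two-sided p-value
#' doubles the smaller exact tail, capped at 1.
#'
#' @param coding,noncoding Non-negative integer counts (vectors recycled
#'   together); each pair must total at least 1.
#' @return Data.frame with `coding`, `noncoding`, `p_value`, and
#'   `direction` in `{coding_depleted, coding_enriched, none}` (by count
#'   imbalance; `none` when equal).
#' @export
test_strand_asymmetry <- function(coding, noncoding) {
  n <- max(length(coding), length(noncoding))
  coding <- rep_len(coding, n); noncoding <- rep_len(noncoding, n)
  stopifnot(all(coding >= 0), all(noncoding >= 0))
  total <- coding + noncoding
  if (any(total < 1)) stop("both strand counts are zero; test undefined")
  lower <- stats::pbinom(coding, total, 0.5)
  upper <- stats::pbinom(coding - 1, total, 0.5, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  data.frame(coding = coding, noncoding = noncoding, p_value = p,
             direction = ifelse(coding < noncoding, "coding_depleted",
                                ifelse(coding > noncoding, "coding_enriched",
                                       "none")),
             stringsAsFactors = FALSE)
}

.class_of_channel <- function(channel) {
  # 16 channels per substitution class, in class order
  sbs_classes()[(channel - 1L) %/% 16L + 1L]
}

#' Strand asymmetry per substitution class and signature
#'
#' From a 192-channel catalog with signature activities, attributes each
#' channel's mutations to signatures (activity-weighted, as in
#' [attribute_mutation()]), sums attributed counts over coding vs noncoding
#' sub-channels within each substitution class, and applies the exact
#' binomial test. Raw class totals (no attribution) are reported as
#' signature `"(all)"`. Attributed counts are rounded to integers for the
#' test.
#'
#' @param signatures_192 192-channel signature matrix W (columns sum to 1).
#' @param activities K x samples activity matrix H aligned with
#'   `catalog_192`'s samples.
#' @param catalog_192 192 x samples count matrix.
#' @param alpha Significance level used only for the reported `direction`
#'   annotation of raw counts (the p-values themselves are unadjusted; a
#'   Benjamini-Hochberg column `p_adjust` is added across classes within
#'   each signature).
#' @return Data.frame: `signature`, `snv_class`, `coding`, `noncoding`,
#'   `p_value`, `direction`, `p_adjust`. Classes with zero attributed mass
#'   for a signature get `NA` p-values.
#' @export
stranded_signature_bias <- function(signatures_192, activities, catalog_192,
                                    alpha = 0.05) {
  W <- as.matrix(signatures_192)
  H <- as.matrix(activities)
  V <- as.matrix(catalog_192)
  if (nrow(W) != 192 || nrow(V) != 192) stop("192-channel inputs required")
  if (!identical(colnames(V), colnames(H)) && ncol(V) != ncol(H)) {
    stop("catalog and activities have different samples")
  }
  if (!is.null(rownames(V)) && !is.null(rownames(W)) &&
      !identical(rownames(V), rownames(W))) {
    stop("catalog and signatures have different channel orderings")
  }
  K <- ncol(W)
  sig_names <- colnames(W)
  if (is.null(sig_names)) sig_names <- paste0("S", seq_len(K))
  ch96 <- rep(seq_len(96), each = 2)
  strand <- rep(c("coding", "noncoding"), times = 96)
  cls <- .class_of_channel(ch96)
  # per-channel, per-sample credit shares, then attributed counts
  attributed <- matrix(0, 192, K)
  for (s in seq_len(ncol(V))) {
    rate <- W * rep(H[, s], each = 192)          # 192 x K
    denom <- rowSums(rate)
    share <- rate / ifelse(denom > 0, denom, 1)  # unattributable rows get 0
    share[denom == 0, ] <- 0
    attributed <- attributed + share * V[, s]
  }
  rows <- list()
  for (k in seq_len(K)) {
    for (cl in sbs_classes()) {
      cod <- round(sum(attributed[cls == cl & strand == "coding", k]))
      non <- round(sum(attributed[cls == cl & strand == "noncoding", k]))
      if (cod + non == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          signature = sig_names[k], snv_class = cl, coding = 0, noncoding = 0,
          p_value = NA_real_, direction = "n/a", stringsAsFactors = FALSE)
      } else {
        t <- test_strand_asymmetry(cod, non)
        rows[[length(rows) + 1]] <- data.frame(
          signature = sig_names[k], snv_class = cl, coding = cod,
          noncoding = non, p_value = t$p_value, direction = t$direction,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (cl in sbs_classes()) {
    cod <- sum(V[cls == cl & strand == "coding", ])
    non <- sum(V[cls == cl & strand == "noncoding", ])
    if (cod + non == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        signature = "(all)", snv_class = cl, coding = 0, noncoding = 0,
        p_value = NA_real_, direction = "n/a", stringsAsFactors = FALSE)
    } else {
      t <- test_strand_asymmetry(cod, non)
      rows[[length(rows) + 1]] <- data.frame(
        signature = "(all)", snv_class = cl, coding = cod, noncoding = non,
        p_value = t$p_value, direction = t$direction, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::ave(out$p_value, out$signature,
                             FUN = function(p) stats::p.adjust(p, "BH"))
  out
}
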