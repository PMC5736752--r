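#' Attribute one mutation's credit across signatures
#'
#' A mutation in channel `c` of a tumor with activity vector `h` gives
#' signature `k` the credit `h_k W[c, k] / sum_j h_j W[c, j]` -- the
#' signature's channel-specific rate weighted by its inferred activity in
#' that tumor. Credits sum to 1. For example, with activities `(10, 90)`
#' and channel rates `(0.05, 0.01)`, signature 1 receives
#' `10*0.05 / (10*0.05 + 90*0.01) = 0.357...`.
#'
#' @param channel Channel index of the mutation (1-based row of `W`).
#' @param W Channels x K signature matrix (columns sum to 1).
#' @param h Length-K non-negative activity vector with positive total.
#' @return Length-K credit vector summing to 1, or all-`NA` when every
#'   signature has zero mass on the channel (unattributable).
#' @export
attribute_mutation <- function(channel, W, h) {
  W <- as.matrix(W)
  stopifnot(length(h) == ncol(W), all(h >= 0), sum(h) > 0,
            channel >= 1, channel <= nrow(W))
  rate <- h * W[channel, ]
  total <- sum(rate)
  if (total == 0) return(rep(NA_real_, length(h)))
  credit <- rate / total
  credit[credit < 1e-12] <- 0
  credit / sum(credit)
}

#' Aggregate clonality-weighted signature attributions over a cohort
#'
#' Applies [attribute_mutation()] to every mutation and sums credit into
#' clonal and subclonal pools per signature. Mutations with unknown
#' clonality or with no attributable signature are excluded and counted.
#'
#' @param mut Mutation data.frame with `sample`, `channel`, and `clonality`
#'   (`"clonal"` / `"subclonal"`; anything else counts as unknown).
#'   Clonality is conventionally derived from subclone CCF: clonal iff the
#'   mutation's subclone has CCF 1 within tolerance (see
#'   [ccf_clonality()]).
#' @param W Channels x K signature matrix.
#' @param H K x samples activity matrix with columns named by sample.
#' @return Data.frame of class `attribution_table`: `signature`,
#'   `clonal_credit`, `subclonal_credit`, `subclonal_fraction`; attributes
#'   `"n_attributed"`, `"n_unknown_clonality"`, `"n_unattributable"`,
#'   `"overall_subclonal_fraction"`.
#' @export
aggregate_attributions <- function(mut, W, H) {
  W <- as.matrix(W); H <- as.matrix(H)
  K <- ncol(W)
  sig_names <- colnames(W)
  if (is.null(sig_names)) sig_names <- paste0("S", seq_len(K))
  known <- mut$clonality %in% c("clonal", "subclonal")
  n_unknown <- sum(!known)
  mut <- mut[known, , drop = FALSE]
  if (is.null(colnames(H))) stop("activity matrix must have sample columns")
  missing_samples <- setdiff(unique(as.character(mut$sample)), colnames(H))
  if (length(missing_samples) > 0) {
    stop("mutations from samples without activity columns: ",
         paste(missing_samples, collapse = ", "))
  }
  clonal <- numeric(K); subclonal <- numeric(K)
  n_unattr <- 0L; n_attr <- 0L
  for (s in unique(as.character(mut$sample))) {
    rows <- mut[mut$sample == s, , drop = FALSE]
    h <- H[, s]
    if (sum(h) <= 0) {
      n_unattr <- n_unattr + nrow(rows)
      next
    }
    rate <- W * rep(h, each = nrow(W))  # channels x K
    denom <- rowSums(rate)
    share <- rate / ifelse(denom > 0, denom, 1)
    share[denom == 0, ] <- NA_real_
    cr <- share[rows$channel, , drop = FALSE]
    bad <- is.na(cr[, 1])
    n_unattr <- n_unattr + sum(bad)
    cr <- cr[!bad, , drop = FALSE]
    is_sub <- rows$clonality[!bad] == "subclonal"
    n_attr <- n_attr + nrow(cr)
    if (any(!is_sub)) clonal <- clonal + colSums(cr[!is_sub, , drop = FALSE])
    if (any(is_sub)) subclonal <- subclonal + colSums(cr[is_sub, , drop = FALSE])
  }
  out <- data.frame(signature = sig_names,
                    clonal_credit = clonal,
                    subclonal_credit = subclonal,
                    subclonal_fraction = ifelse(clonal + subclonal > 0,
                                                subclonal / (clonal + subclonal),
                                                NA_real_),
                    stringsAsFactors = FALSE)
  attr(out, "n_attributed") <- n_attr
  attr(out, "n_unknown_clonality") <- n_unknown
  attr(out, "n_unattributable") <- n_unattr
  attr(out, "overall_subclonal_fraction") <-
    sum(subclonal) / max(sum(clonal) + sum(subclonal), .Machine$double.eps)
  class(out) <- c("attribution_table", class(out))
  out
}

#' Clonality from subclone cancer cell fraction
#'
#' A mutation is clonal when its subclone's CCF equals 1 within tolerance,
#' subclonal when below, unknown when missing.
#'
#' @param ccf Numeric CCF vector in `[0, 1]`, `NA` allowed.
#' @param tol Tolerance around 1 (default 1e-3).
#' @return Character vector in `{clonal, subclonal, unknown}`.
#' @export
ccf_clonality <- function(ccf, tol = 1e-3) {
  ifelse(is.na(ccf), "unknown",
         ifelse(abs(ccf - 1) <= tol, "clonal", "subclonal"))
}

#' Chi-squared test for subclonal enrichment across signatures
#'
#' Pearson chi-squared test of homogeneity of the subclonal proportion on
#' the K x 2 clonal/subclonal credit table, with `df = K - 1`. Credits are
#' real-valued attribution mass treated as counts. Signatures with zero
#' total credit are dropped with a warning (reducing `df`).
#'
#' @param table An `attribution_table` from [aggregate_attributions()], or
#'   any data.frame with `clonal_credit` and `subclonal_credit` columns.
#' @return List: `statistic`, `df`, `p_value`, `n_signatures`.
#' @export
subclonal_enrichment_test <- function(table) {
  O <- cbind(table$clonal_credit, table$subclonal_credit)
  zero <- rowSums(O) == 0
  if (any(zero)) {
    warning(sum(zero), " signature(s) with zero total credit dropped")
    O <- O[!zero, , drop = FALSE]
  }
  K <- nrow(O)
  if (K < 2) stop("need at least two signatures with credit")
  if (sum(O) <= 0) stop("total credit is zero")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  df <- K - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       n_signatures = K)
}
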