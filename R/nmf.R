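.init_factors <- function(V, rank) {
  n_ch <- nrow(V); n_s <- ncol(V)
  W0 <- matrix(stats::runif(n_ch * rank), n_ch, rank)
  W0 <- sweep(W0, 2, colSums(W0), "/")
  # uniform activities scaled so the initial product carries the catalog mass
  H0 <- matrix(stats::runif(rank * n_s), rank, n_s) * (2 * sum(V) / (n_s * rank))
  list(W = W0, H = H0)
}

.normalize_factors <- function(W, H) {
  cs <- colSums(W)
  cs[cs == 0] <- 1
  list(W = sweep(W, 2, cs, "/"), H = H * cs)
}

#' De-novo mutational signature discovery by multi-run NMF
#'
#' Factorizes a channels-by-samples catalog `V` into non-negative signatures
#' `W` (columns summing to 1) and activities `H` (mutation-count scale) with
#' KL-divergence multiplicative updates (the Brunet rules). Because the
#' factorization is non-deterministic, `n_runs` independent runs are
#' performed from seeded random starts and the run with the minimum
#' Frobenius residual `||V - WH||` is returned.
#'
#' @param catalog Numeric channels x samples matrix (96 or 192 channels).
#' @param rank Number of signatures; must be below both dimensions.
#' @param n_runs Number of independent runs (default 200).
#' @param seed Base seed; run `r` uses `seed + r - 1`.
#' @param max_iter Iteration cap per run (default 2000).
#' @param rel_tol Stop a run when the relative change of the residual falls
#'   below this (default 1e-6).
#' @return A list of class `signature_discovery`: `signatures` (W, columns
#'   renormalized to 1), `activities` (H, compensating row scale),
#'   `residual` (Frobenius), `rss`, `trace` (per-iteration `residual` and
#'   `divergence` of the best run), `best_run_seed`, `run_residuals`.
#' @export
discover_signatures <- function(catalog, rank, n_runs = 200, seed = 1,
                                max_iter = 2000, rel_tol = 1e-6) {
  V <- as.matrix(catalog)
  if (sum(V) <= 0) stop("catalog has zero total mass")
  if (rank < 1 || rank >= min(dim(V))) {
    stop("rank must be at least 1 and below min(channels, samples)")
  }
  best <- NULL
  run_residuals <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r - 1
    init <- withr::with_seed(run_seed, .init_factors(V, rank))
    fit <- cpp_nmf_kl_run(V, init$W, init$H, max_iter, rel_tol, 1e-12)
    run_residuals[r] <- utils::tail(fit$residual_trace, 1)
    if (is.null(best) || run_residuals[r] < best$residual) {
      best <- list(fit = fit, residual = run_residuals[r], seed = run_seed)
    }
  }
  fac <- .normalize_factors(best$fit$W, best$fit$H)
  rownames(fac$W) <- rownames(V)
  colnames(fac$W) <- rownames(fac$H) <- paste0("S", seq_len(rank))
  colnames(fac$H) <- colnames(V)
  structure(list(signatures = fac$W,
                 activities = fac$H,
                 residual = best$residual,
                 rss = best$residual^2,
                 trace = data.frame(iteration = seq_along(best$fit$residual_trace),
                                    residual = best$fit$residual_trace,
                                    divergence = best$fit$divergence_trace),
                 best_run_seed = best$seed,
                 run_residuals = run_residuals,
                 rank = rank),
            class = "signature_discovery")
}

#' Rank survey for manual selection of the number of signatures
#'
#' Runs `n_runs` seeded factorizations at each candidate rank and reports
#' the diagnostics used for manual rank selection: the cophenetic
#' correlation of the consensus over runs (samples co-cluster when they
#' share a dominant signature), the minimum Frobenius residual, and its
#' residual sum of squares. Rank choice is deliberately not automated.
#'
#' @inheritParams discover_signatures
#' @param ranks Integer vector of candidate ranks (conventionally 2--8).
#' @param n_runs Runs per rank (default 50).
#' @return Data.frame with one row per rank: `rank`, `cophenetic`, `rss`,
#'   `residual`, `best_run_seed`.
#' @export
rank_survey <- function(catalog, ranks = 2:8, n_runs = 50, seed = 1,
                        max_iter = 2000, rel_tol = 1e-6) {
  V <- as.matrix(catalog)
  n_s <- ncol(V)
  out <- data.frame(rank = ranks, cophenetic = NA_real_, rss = NA_real_,
                    residual = NA_real_, best_run_seed = NA_integer_)
  for (ri in seq_along(ranks)) {
    rank <- ranks[ri]
    if (rank < 1 || rank >= min(dim(V))) {
      stop("rank ", rank, " is invalid for a ", nrow(V), " x ", n_s, " catalog")
    }
    consensus <- matrix(0, n_s, n_s)
    best_res <- Inf
    best_seed <- NA_integer_
    for (r in seq_len(n_runs)) {
      run_seed <- seed + (ri - 1L) * n_runs + r - 1L
      init <- withr::with_seed(run_seed, .init_factors(V, rank))
      fit <- cpp_nmf_kl_run(V, init$W, init$H, max_iter, rel_tol, 1e-12)
      res <- utils::tail(fit$residual_trace, 1)
      if (res < best_res) {
        best_res <- res
        best_seed <- run_seed
      }
      cl <- apply(fit$H, 2, which.max)
      consensus <- consensus + outer(cl, cl, "==")
    }
    consensus <- consensus / n_runs
    d <- stats::as.dist(1 - consensus)
    coph <- if (stats::sd(d) == 0) {
      1.0  # all runs cluster samples identically
    } else {
      stats::cor(d, stats::cophenetic(stats::hclust(d, method = "average")))
    }
    out$cophenetic[ri] <- coph
    out$rss[ri] <- best_res^2
    out$residual[ri] <- best_res
    out$best_run_seed[ri] <- best_seed
  }
  out
}

#' Cosine similarity between two channel vectors
#'
#' @param a,b Non-negative numeric vectors of equal length.
#' @return `sum(a*b) / (||a|| ||b||)`, in `[0, 1]` for non-negative input.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity is undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Match discovered signatures to a reference panel by cosine similarity
#'
#' Each discovered signature is paired with its most cosine-similar
#' reference signature; the match is accepted when the similarity reaches
#' `threshold` (0.85 by convention), otherwise the signature is labeled
#' `"UNK"`. Optionally also reports similarity to the mean of named
#' reference pairs, since some mutational processes (e.g. APOBEC) are
#' described by a pair of published signatures.
#'
#' @param discovered,reference Channels x signatures matrices with the same
#'   channel ordering (checked via rownames when present).
#' @param threshold Cosine similarity required to accept a match.
#' @param pairs Optional list of length-2 character vectors of reference
#'   signature names; a `mean(a+b)` similarity column is added per pair.
#' @return Data.frame with `signature`, `best_match`, `cosine`, `matched`,
#'   `label`, `tie`, plus one column per requested pair mean.
#' @export
match_signatures <- function(discovered, reference, threshold = 0.85,
                             pairs = NULL) {
  discovered <- as.matrix(discovered); reference <- as.matrix(reference)
  if (nrow(discovered) != nrow(reference)) {
    stop("discovered and reference panels have different channel counts")
  }
  if (!is.null(rownames(discovered)) && !is.null(rownames(reference)) &&
      !identical(rownames(discovered), rownames(reference))) {
    stop("discovered and reference panels have different channel orderings")
  }
  kd <- ncol(discovered); kr <- ncol(reference)
  cs <- matrix(NA_real_, kd, kr)
  for (i in seq_len(kd)) {
    for (j in seq_len(kr)) {
      cs[i, j] <- cosine_similarity(discovered[, i], reference[, j])
    }
  }
  best <- apply(cs, 1, which.max)  # which.max takes the lower index on ties
  best_cos <- cs[cbind(seq_len(kd), best)]
  tie <- vapply(seq_len(kd), function(i) {
    sum(abs(cs[i, ] - best_cos[i]) < 1e-12) > 1
  }, logical(1))
  ref_names <- colnames(reference)
  if (is.null(ref_names)) ref_names <- paste0("R", seq_len(kr))
  disc_names <- colnames(discovered)
  if (is.null(disc_names)) disc_names <- paste0("S", seq_len(kd))
  out <- data.frame(signature = disc_names,
                    best_match = ref_names[best],
                    cosine = best_cos,
                    matched = best_cos >= threshold,
                    label = ifelse(best_cos >= threshold, ref_names[best], "UNK"),
                    tie = tie,
                    stringsAsFactors = FALSE)
  for (p in pairs) {
    if (!all(p %in% ref_names)) stop("pair members not in reference panel")
    mean_sig <- rowMeans(reference[, p, drop = FALSE])
    col <- paste0("mean(", paste(p, collapse = "+"), ")")
    out[[col]] <- vapply(seq_len(kd), function(i) {
      cosine_similarity(discovered[, i], mean_sig)
    }, numeric(1))
  }
  out
}

#' Bar plot of a 96-channel signature
#'
#' @param sig Numeric vector of length 96 (channel order as in
#'   [channel_labels()]).
#' @param main Plot title.
#' @export
plot_signature <- function(sig, main = "") {
  stopifnot(length(sig) == 96)
  cols <- rep(c("#03BCEE", "#010101", "#E32926", "#CAC9C9", "#A1CE63",
                "#EBC6C4"), each = 16)
  graphics::barplot(sig, col = cols, border = NA, names.arg = rep("", 96),
                    main = main, ylab = "fraction of mutations")
  graphics::mtext(sbs_classes(), side = 1, at = (0:5) * 19.2 + 9.6, line = 0.5,
                  cex = 0.8)
}
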