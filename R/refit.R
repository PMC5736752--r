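#' Configuration for fixed-signature activity refitting
#'
#' The stopping rule watches the Frobenius error `||V - WH_i||` for
#' horizontal asymptote behavior: iteration stops when the average
#' per-iteration drop over the last `window` iterations,
#' `(err[i - window] - err[i]) / window`, falls below `tol`.
#'
#' @param tol Asymptote slope threshold (default 1e-4).
#' @param window Window length in iterations (default 20).
#' @param max_iter Hard iteration cap guarding non-terminating settings
#'   (default 10000).
#' @param seed Seed for the random initial activity matrix.
#' @return A `refit_config` list.
#' @export
refit_config <- function(tol = 1e-4, window = 20, max_iter = 10000, seed = 1) {
  stopifnot(tol > 0, window >= 1, max_iter > window)
  structure(list(tol = tol, window = window, max_iter = max_iter, seed = seed),
            class = "refit_config")
}

#' Infer activities of a fixed signature set in individual tumors
#'
#' Given a catalog `V` and fixed signatures `W` (columns summing to 1),
#' starts from a random non-negative activity matrix `H_0` and applies the
#' multiplicative H-update of the KL-divergence NMF rules; `W` is never
#' updated. Iteration stops under the windowed asymptote rule of
#' [refit_config()], or at `max_iter` with a warning.
#'
#' @param catalog Channels x samples numeric matrix `V`.
#' @param signatures Channels x K matrix `W`, same channel ordering as the
#'   catalog (checked via rownames when present).
#' @param config A [refit_config()].
#' @return List of class `activity_fit`: `activities` (K x samples matrix
#'   `H`), `trace` (per-iteration `residual` and `divergence`), `converged`,
#'   `iterations`.
#' @export
infer_activities <- function(catalog, signatures, config = refit_config()) {
  V <- as.matrix(catalog)
  W <- as.matrix(signatures)
  if (nrow(V) != nrow(W)) stop("catalog and signatures have different channel counts")
  if (!is.null(rownames(V)) && !is.null(rownames(W)) &&
      !identical(rownames(V), rownames(W))) {
    stop("catalog and signatures have different channel orderings")
  }
  K <- ncol(W); n_s <- ncol(V)
  # scale-appropriate start: sample total split uniformly over signatures
  H0 <- withr::with_seed(config$seed, {
    matrix(stats::runif(K * n_s), K, n_s) *
      rep(pmax(colSums(V), 1) / K, each = K) * 2
  })
  fit <- cpp_refit_kl(V, W, H0, config$tol, config$window, config$max_iter,
                      1e-12)
  if (!fit$converged) {
    warning("refit reached max_iter = ", config$max_iter,
            " without meeting the asymptote rule")
  }
  H <- fit$H
  H[H < 1e-12] <- 0
  rownames(H) <- colnames(W)
  colnames(H) <- colnames(V)
  structure(list(activities = H,
                 trace = data.frame(iteration = seq_along(fit$residual_trace),
                                    residual = fit$residual_trace,
                                    divergence = fit$divergence_trace),
                 converged = fit$converged,
                 iterations = fit$iterations),
            class = "activity_fit")
}

#' Per-sample and cohort signature activity fractions
#'
#' Converts an activity matrix (mutation-count scale) into the fraction of
#' each sample's mutations attributed to each signature, and the cohort-wide
#' fraction (total signature mass over total mass).
#'
#' @param H K x samples non-negative activity matrix (or an `activity_fit`).
#' @return List with `per_sample` (K x samples, columns summing to 1;
#'   all-zero samples give NaN columns) and `cohort` (length-K vector
#'   summing to 1).
#' @export
attribute_activity_fractions <- function(H) {
  if (inherits(H, "activity_fit")) H <- H$activities
  H <- as.matrix(H)
  if (any(H < 0)) stop("activities must be non-negative")
  total <- sum(H)
  if (total <= 0) stop("activity matrix has zero total mass")
  per_sample <- sweep(H, 2, colSums(H), "/")
  list(per_sample = per_sample, cohort = rowSums(H) / total)
}
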