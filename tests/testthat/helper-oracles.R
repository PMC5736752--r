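# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths (plain-R loops,
# direct enumeration) so they can serve as cross-checks.

# Plain-R KL-divergence multiplicative updates (independent of the compiled
# core): returns the Frobenius residual after `iters` iterations.
r_kl_nmf_residual <- function(V, W, H, iters, update_w = TRUE) {
  eps <- 1e-12
  for (it in seq_len(iters)) {
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / (colSums(W) + eps)
    if (update_w) {
      WH <- W %*% H + eps
      W <- W * ((V / WH) %*% t(H)) /
        matrix(rowSums(H) + eps, nrow(W), ncol(W), byrow = TRUE)
    }
  }
  sqrt(sum((V - W %*% H)^2))
}

# Exact two-sided binomial p by direct enumeration (double the smaller tail).
binom_two_sided_oracle <- function(k, n) {
  probs <- vapply(0:n, function(x) choose(n, x) * 0.5^n, numeric(1))
  lower <- sum(probs[seq_len(k + 1)])
  upper <- sum(probs[seq(k + 1, n + 1)])
  min(1, 2 * min(lower, upper))
}

# Multinomial catalog with known signatures and exposures (counts scale).
make_planted_catalog <- function(W, H, seed = 1) {
  withr::with_seed(seed, {
    V <- matrix(0, nrow(W), ncol(H))
    for (s in seq_len(ncol(H))) {
      for (k in seq_len(ncol(W))) {
        n_k <- round(H[k, s])
        if (n_k > 0) {
          draws <- sample.int(nrow(W), n_k, replace = TRUE, prob = W[, k])
          V[, s] <- V[, s] + tabulate(draws, nbins = nrow(W))
        }
      }
    }
    rownames(V) <- rownames(W)
    colnames(V) <- paste0("s", seq_len(ncol(H)))
    V
  })
}

# Greedy matching of discovered to true signatures by cosine similarity.
match_to_truth <- function(discovered, truth) {
  vapply(seq_len(ncol(truth)), function(j) {
    max(vapply(seq_len(ncol(discovered)), function(i) {
      cosine_similarity(discovered[, i], truth[, j])
    }, numeric(1)))
  }, numeric(1))
}

extdata <- function(f) system.file("extdata", f, package = "platsig")
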