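flat_freq <- function() {
  f <- rep(1 / 32, 32)
  names(f) <- pyrimidine_contexts()
  f
}

test_that("signature renormalization follows the ratio-and-rescale rule", {
  sig <- withr::with_seed(1, {
    s <- rgamma(96, 0.5)
    s / sum(s)
  })
  f <- flat_freq()
  expect_equal(unname(renormalize_signature(sig, f, f)), unname(sig),
               tolerance = 1e-12)

  # hand example on two channels with distinct contexts: ACA and ACC carry
  # mass 0.5 each; source freqs (.2, .2), target (.1, .3) -> (0.25, 0.75)
  sig2 <- numeric(96)
  names(sig2) <- channel_labels()
  sig2["A[C>A]A"] <- 0.5
  sig2["A[C>A]C"] <- 0.5
  src <- flat_freq(); tgt <- flat_freq()
  src["ACA"] <- 0.2; src["ACC"] <- 0.2
  tgt["ACA"] <- 0.1; tgt["ACC"] <- 0.3
  out <- renormalize_signature(sig2, src, tgt)
  expect_equal(unname(out["A[C>A]A"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(out["A[C>A]C"]), 0.75, tolerance = 1e-12)
})

test_that("renormalization round-trips and stays on the simplex", {
  withr::with_seed(2, {
    for (rep in 1:5) {
      sig <- rgamma(96, 0.5); sig <- sig / sum(sig)
      src <- rgamma(32, 2); src <- src / sum(src); names(src) <- pyrimidine_contexts()
      tgt <- rgamma(32, 2); tgt <- tgt / sum(tgt); names(tgt) <- pyrimidine_contexts()
      fwd <- renormalize_signature(sig, src, tgt)
      expect_equal(sum(fwd), 1, tolerance = 1e-12)
      expect_true(all(fwd >= 0))
      back <- renormalize_signature(fwd, tgt, src)
      expect_equal(unname(back), unname(sig), tolerance = 1e-9)
    }
  })
})

test_that("renormalization refuses silent drops at zero source frequency", {
  sig <- numeric(96); sig[1] <- 1
  src <- flat_freq(); src["ACA"] <- 0
  expect_error(renormalize_signature(sig, src, flat_freq()),
               "zero source frequency")
})

test_that("substituting a signature for itself reproduces its activities", {
  W <- generate_signatures(3, seed = 3)
  H <- withr::with_seed(4, matrix(runif(3 * 15, 100, 800), 3, 15))
  V <- make_planted_catalog(W, H, seed = 5)
  colnames(V) <- paste0("s", 1:15)
  res <- substitute_and_correlate(V, W, "S2", W[, "S2"],
                                  refit_config(seed = 6))
  expect_gte(res$r, 0.999)
  expect_equal(res$flag, "ok")
})

test_that("a noisy candidate correlates strongly with the true spectrum", {
  truth <- generate_signatures(3, seed = 7)
  noisy <- withr::with_seed(8, {
    x <- truth[, 3] + rgamma(96, 0.25) * 0.004
    x / sum(x)
  })
  expect_gt(cosine_similarity(noisy, truth[, 3]), 0.85)
  H <- withr::with_seed(9, matrix(runif(3 * 30, 50, 700), 3, 30))
  V <- make_planted_catalog(truth, H, seed = 10)
  W <- truth
  W[, 3] <- noisy
  colnames(W)[3] <- "CAND"
  res <- substitute_and_correlate(V, W, "CAND", truth[, 3],
                                  refit_config(seed = 11))
  expect_gte(res$r, 0.9)
})

test_that("a replacement with no catalog support is flagged", {
  W <- generate_signatures(2, seed = 12)
  # catalog supported only on the first 48 channels
  V <- withr::with_seed(13, rbind(matrix(rpois(48 * 6, 10), 48, 6),
                                  matrix(0, 48, 6)))
  repl <- c(numeric(48), rep(1 / 48, 48))
  res <- substitute_and_correlate(V, W, "S1", repl, refit_config(seed = 14))
  expect_true(res$flag == "constant_activity" ||
                max(res$replacement_activity) < 1e-6 * sum(V))
})

test_that("permutation surrogates preserve entries / simplex membership", {
  repl <- withr::with_seed(15, {
    s <- rgamma(96, 0.5)
    s / sum(s)
  })
  perms <- platsig:::.draw_surrogates(repl, "permute_channels", 20, NULL, 16)
  for (p in perms) expect_equal(sort(p), sort(repl))
  expect_identical(perms,
                   platsig:::.draw_surrogates(repl, "permute_channels", 20,
                                              NULL, 16))
  panel <- generate_signatures(5, seed = 17)
  combos <- platsig:::.draw_surrogates(repl, "reference_combination", 20,
                                       panel, 18)
  for (s in combos) {
    expect_equal(sum(s), 1, tolerance = 1e-12)
    expect_true(all(s >= 0))
  }
})

test_that("empirical p-values are definitional at the extremes", {
  truth <- generate_signatures(3, seed = 19)
  H <- withr::with_seed(20, matrix(runif(3 * 12, 100, 900), 3, 12))
  V <- make_planted_catalog(truth, H, seed = 21)
  colnames(truth)[3] <- "CAND"
  # candidate is the planted signature itself: observed r ~ 1 beats a
  # channel-permutation null
  nd <- suppressWarnings(
    permutation_null(V, truth, "CAND", truth[, "CAND"],
                     method = "permute_channels", n = 60,
                     config = refit_config(seed = 22), seed = 23))
  expect_equal(nd$empirical_p, mean(nd$values >= nd$observed, na.rm = TRUE))
  expect_lte(nd$empirical_p, 0.05)
  # flipping the roles: an observed value below the whole null gives p = 1
  expect_equal(mean(nd$values >= min(nd$values) - 1), 1)
  # and above the whole null gives p = 0
  expect_equal(mean(nd$values >= max(nd$values) + 1), 0)
})

test_that("the reference-combination null requires a usable panel", {
  truth <- generate_signatures(3, seed = 24)
  V <- make_planted_catalog(truth,
                            withr::with_seed(25, matrix(runif(3 * 6, 100, 500),
                                                        3, 6)),
                            seed = 26)
  expect_error(permutation_null(V, truth, "S1", truth[, 1],
                                method = "reference_combination", n = 200),
               "reference panel")
})
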