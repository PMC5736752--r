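test_that("an exact rank-1 catalog is recovered with near-zero residual", {
  sig <- withr::with_seed(1, {
    s <- rgamma(96, 0.5)
    s / sum(s)
  })
  loads <- seq(100, 1000, length.out = 8)
  V <- outer(sig, loads)
  d <- discover_signatures(V, rank = 1, n_runs = 5, seed = 1)
  expect_gte(cosine_similarity(d$signatures[, 1], sig), 0.999)
  expect_lt(d$residual, 1e-4 * sqrt(sum(V^2)))
})

test_that("two planted disjoint-support signatures are recovered", {
  W <- matrix(0, 96, 2)
  W[1:48, 1] <- withr::with_seed(2, rgamma(48, 1))
  W[49:96, 2] <- withr::with_seed(3, rgamma(48, 1))
  W <- sweep(W, 2, colSums(W), "/")
  H <- withr::with_seed(4, matrix(runif(2 * 20, 100, 900), 2, 20))
  V <- make_planted_catalog(W, H, seed = 5)
  d <- discover_signatures(V, rank = 2, n_runs = 20, seed = 1)
  expect_true(all(match_to_truth(d$signatures, W) >= 0.95))
})

test_that("discovery is deterministic for a fixed seed", {
  V <- withr::with_seed(6, matrix(rpois(96 * 8, 4), 96, 8))
  d1 <- discover_signatures(V, 2, n_runs = 5, seed = 42)
  d2 <- discover_signatures(V, 2, n_runs = 5, seed = 42)
  expect_identical(d1$signatures, d2$signatures)
  expect_identical(d1$activities, d2$activities)
  expect_identical(d1$best_run_seed, d2$best_run_seed)
})

test_that("discovery rejects invalid ranks and empty catalogs", {
  V <- matrix(1, 96, 5)
  expect_error(discover_signatures(V, 5, n_runs = 1), "rank")
  expect_error(discover_signatures(matrix(0, 96, 5), 2, n_runs = 1), "mass")
})

test_that("the compiled updates agree with a plain-R oracle", {
  V <- withr::with_seed(8, matrix(rpois(96 * 10, 6), 96, 10))
  rank <- 3
  d <- discover_signatures(V, rank, n_runs = 1, seed = 7, max_iter = 200,
                           rel_tol = 0)
  init <- withr::with_seed(7, platsig:::.init_factors(V, rank))
  oracle_res <- r_kl_nmf_residual(V, init$W, init$H, iters = 200)
  expect_equal(d$residual, oracle_res, tolerance = 0.01)
})

test_that("rank survey reports diagnostics for manual rank choice", {
  W <- generate_signatures(2, seed = 9, max_cosine = 0.5)
  # each sample clearly dominated by one signature, so the planted rank
  # clusters samples stably while a larger rank has no stable split
  H <- withr::with_seed(10, {
    dom <- rep(1:2, length.out = 15)
    h <- matrix(runif(2 * 15, 50, 150), 2, 15)
    h[cbind(dom, 1:15)] <- runif(15, 700, 1200)
    h
  })
  V <- W %*% H  # exact rank-2 catalog
  surv <- rank_survey(V, ranks = 2:4, n_runs = 15, seed = 1)
  expect_equal(nrow(surv), 3)
  # the planted rank explains the data nearly as well as larger ranks and
  # clusters more stably
  expect_lt(surv$residual[1] - surv$residual[2],
            0.01 * sqrt(sum(V^2)))
  expect_gte(surv$cophenetic[1] + 1e-9, surv$cophenetic[2])

  one <- rank_survey(V, ranks = 2, n_runs = 5, seed = 1)
  expect_equal(nrow(one), 1)

  dup <- V[, rep(1, 6)]
  colnames(dup) <- paste0("d", 1:6)
  degenerate <- rank_survey(dup, ranks = 1, n_runs = 5, seed = 1)
  expect_equal(degenerate$cophenetic, 1.0)
})

test_that("cosine similarity follows the dot-product formula", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosine_similarity(c(1, 1, 0), 7 * c(1, 1, 0)), 1)  # scale-free
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(1:3, 1:4), "length")
})

test_that("signature matching applies the 0.85 threshold and pair means", {
  ref <- generate_signatures(4, seed = 12)
  disc <- cbind(ref[, 2], withr::with_seed(13, {
    s <- rgamma(96, 0.5)
    s / sum(s)
  }))
  colnames(disc) <- c("D1", "D2")
  rownames(disc) <- rownames(ref)
  m <- match_signatures(disc, ref)
  expect_equal(m$best_match[1], "S2")
  expect_equal(m$cosine[1], 1, tolerance = 1e-12)
  expect_true(m$matched[1])
  expect_equal(m$label[2], "UNK")

  # a half-half blend is closer to the pair mean than to either member
  for (seed in 14:16) {
    refs <- generate_signatures(3, seed = seed)
    blend <- 0.5 * (refs[, 1] + refs[, 2])
    mm <- match_signatures(matrix(blend, dimnames = list(rownames(refs), "B")),
                           refs, pairs = list(c("S1", "S2")))
    pair_col <- mm[["mean(S1+S2)"]]
    expect_gt(pair_col, cosine_similarity(blend, refs[, 1]))
    expect_gt(pair_col, cosine_similarity(blend, refs[, 2]))
  }

  bad <- ref
  rownames(bad) <- rev(rownames(ref))
  expect_error(match_signatures(disc, bad), "ordering")
})
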