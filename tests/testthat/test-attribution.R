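test_that("per-mutation credit follows the activity-weighted rule", {
  W <- matrix(c(0.05, 0.95, 0.01, 0.99), 2, 2)
  cr <- attribute_mutation(1, W, c(10, 90))
  expect_equal(cr[1], 10 * 0.05 / (10 * 0.05 + 90 * 0.01), tolerance = 1e-12)
  expect_equal(sum(cr), 1)

  # equal activities and equal channel rates split evenly
  W4 <- matrix(1 / 96, 96, 4)
  expect_equal(attribute_mutation(10, W4, rep(5, 4)), rep(0.25, 4))

  # zero channel rate means zero credit
  W0 <- cbind(c(0.5, 0.5), c(0, 1))
  expect_equal(attribute_mutation(1, W0, c(1, 1))[2], 0)

  # invariance to rescaling the activity vector
  cr2 <- attribute_mutation(1, W, 1000 * c(10, 90))
  expect_equal(cr, cr2, tolerance = 1e-12)

  # unattributable channel
  Wz <- cbind(c(0, 1), c(0, 1))
  expect_true(all(is.na(attribute_mutation(1, Wz, c(1, 1)))))
})

test_that("aggregation pools clonal and subclonal credit conservatively", {
  W <- generate_signatures(2, seed = 1)
  H <- matrix(c(10, 90), 2, 1, dimnames = list(colnames(W), "s1"))
  mut <- data.frame(sample = "s1",
                    channel = withr::with_seed(2, sample.int(96, 40, TRUE)),
                    clonality = rep(c("clonal", "subclonal"), 20))
  tab <- aggregate_attributions(mut, W, H)
  expect_equal(sum(tab$clonal_credit) + sum(tab$subclonal_credit),
               attr(tab, "n_attributed"), tolerance = 1e-6)
  expect_equal(attr(tab, "n_attributed"), 40)

  all_clonal <- transform(mut, clonality = "clonal")
  tab2 <- aggregate_attributions(all_clonal, W, H)
  expect_true(all(tab2$subclonal_fraction == 0))

  # a single subclonal mutation reproduces the worked credit, aggregated
  Wp <- matrix(c(0.05, 0.95, 0.01, 0.99), 2, 2,
               dimnames = list(NULL, c("S1", "S2")))
  one <- data.frame(sample = "s1", channel = 1, clonality = "subclonal")
  tab3 <- aggregate_attributions(one, Wp,
                                 matrix(c(10, 90), 2, 1,
                                        dimnames = list(c("S1", "S2"), "s1")))
  expect_equal(tab3$subclonal_credit, c(0.3571, 0.6429), tolerance = 1e-4)

  unknown <- transform(mut, clonality = "unknown")
  expect_error(expect_gt(nrow(aggregate_attributions(unknown, W, H)), 0),
               NA)  # runs, excluding all
  expect_equal(attr(aggregate_attributions(unknown, W, H),
                    "n_unknown_clonality"), 40)
})

test_that("a subclonally confined signature ranks most subclonal", {
  cfg <- simulation_config(n_patients = 6, mutations_per_tumor = 1000,
                           seed = 3)
  cohort <- generate_paired_cohort(cfg)
  post <- mutation_channels(cohort$post)
  V <- build_catalog(post)
  fit <- infer_activities(V, cohort$truth$signatures, refit_config(seed = 4))
  tab <- aggregate_attributions(post, cohort$truth$signatures,
                                fit$activities)
  trt <- tab$subclonal_fraction[tab$signature == "TRT"]
  expect_equal(which.max(tab$subclonal_fraction),
               which(tab$signature == "TRT"))
  expect_gt(trt, attr(tab, "overall_subclonal_fraction"))
})

test_that("the enrichment chi-squared matches the textbook statistic", {
  same <- data.frame(signature = c("A", "B"),
                     clonal_credit = c(70, 140),
                     subclonal_credit = c(30, 60))
  r <- subclonal_enrichment_test(same)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)

  tab <- data.frame(signature = c("A", "B"),
                    clonal_credit = c(50, 90),
                    subclonal_credit = c(50, 10))
  r2 <- subclonal_enrichment_test(tab)
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(50, 90, 50, 10), 2), correct = FALSE))
  expect_equal(r2$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(r2$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(r2$df, 1)

  four <- data.frame(signature = letters[1:4],
                     clonal_credit = c(100, 80, 60, 40),
                     subclonal_credit = c(20, 30, 40, 50))
  expect_equal(subclonal_enrichment_test(four)$df, 3)

  with_zero <- rbind(four, data.frame(signature = "e", clonal_credit = 0,
                                      subclonal_credit = 0))
  expect_warning(r3 <- subclonal_enrichment_test(with_zero), "zero total")
  expect_equal(r3$df, 3)
})

test_that("the enrichment test holds its nominal level without association", {
  rate <- withr::with_seed(5, {
    rejections <- vapply(seq_len(1000), function(i) {
      sig <- sample.int(3, 400, TRUE, prob = c(0.5, 0.3, 0.2))
      sub <- stats::runif(400) < 0.3
      tab <- data.frame(signature = 1:3,
                        clonal_credit = tabulate(sig[!sub], 3),
                        subclonal_credit = tabulate(sig[sub], 3))
      subclonal_enrichment_test(tab)$p_value < 0.05
    }, logical(1))
    mean(rejections)
  })
  expect_lt(abs(rate - 0.05), 0.025)
})

test_that("clonality labels derive from subclone CCF", {
  expect_equal(ccf_clonality(c(1, 0.9995, 0.7, NA)),
               c("clonal", "clonal", "subclonal", "unknown"))
})
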