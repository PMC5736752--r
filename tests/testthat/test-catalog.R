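test_that("pyrimidine collapsing maps known motifs to their channels", {
  expect_equal(collapse_to_pyrimidine("C", "A", "A", "A")$label, "A[C>A]A")
  expect_equal(collapse_to_pyrimidine("G", "T", "T", "T")$label, "A[C>A]A")
  expect_equal(collapse_to_pyrimidine("T", "G", "C", "G")$label, "C[T>G]G")
  expect_equal(collapse_to_pyrimidine("C", "A", "A", "A")$channel, 1L)
  expect_error(collapse_to_pyrimidine("N", "A", "C", "C"), "invalid")
  expect_error(collapse_to_pyrimidine("C", "C", "A", "A"), "differ")
})

test_that("collapsing is reverse-complement invariant over all raw motifs", {
  comp <- function(b) chartr("ACGT", "TGCA", b)
  bases <- c("A", "C", "G", "T")
  labels <- character(0)
  for (ref in bases) for (alt in setdiff(bases, ref)) {
    for (f5 in bases) for (f3 in bases) {
      fwd <- collapse_to_pyrimidine(ref, alt, f5, f3)
      rev <- collapse_to_pyrimidine(comp(ref), comp(alt), comp(f3), comp(f5))
      expect_identical(fwd$channel, rev$channel)
      labels <- c(labels, fwd$label)
    }
  }
  expect_setequal(labels, channel_labels())
  expect_length(unique(labels), 96)
})

test_that("catalog building conserves counts and handles empty input", {
  mut <- data.frame(sample = "T1", chrom = "chr1", pos = 5, ref = "C",
                    alt = "A", context5 = "A", context3 = "A")
  cat1 <- build_catalog(mut)
  expect_equal(sum(cat1), 1)
  expect_equal(cat1["A[C>A]A", "T1"], 1L)

  empty <- mut[0, ]
  cat0 <- build_catalog(empty, samples = c("T1", "T2"))
  expect_equal(dim(cat0), c(96L, 2L))
  expect_true(all(cat0 == 0))

  cfg <- simulation_config(n_patients = 2, mutations_per_tumor = 500, seed = 3)
  cohort <- generate_paired_cohort(cfg)
  truth_pre <- cohort$truth$mutations[cohort$truth$mutations$ccf_pre > 0, ]
  truth_pre$sample <- paste0(truth_pre$patient, "_pre")
  catp <- build_catalog(truth_pre)
  expect_true(all(colSums(catp) == 500))
})

test_that("context extraction matches the reference and flags mismatches", {
  ref <- read_reference(extdata("synthetic_reference.fa"))
  mut <- read_mutations(extdata("synthetic_mutations.tsv"))
  expect_equal(attr(mut, "qc")$n_non_snv, 1)  # the planted indel
  expect_warning(ctx <- extract_context(mut, ref), "ref allele")
  expect_equal(attr(ctx, "qc")$n_ref_mismatch, 1)
  # every retained context equals the literal flanking bases
  for (i in seq_len(nrow(ctx))) {
    s <- as.character(ref[[ctx$chrom[i]]])
    expect_equal(ctx$context5[i], substr(s, ctx$pos[i] - 1, ctx$pos[i] - 1))
    expect_equal(ctx$context3[i], substr(s, ctx$pos[i] + 1, ctx$pos[i] + 1))
  }
  expect_warning(cat96 <- build_catalog(mut, reference = ref), "ref allele")
  expect_equal(sum(cat96), nrow(ctx))
})

test_that("stranded catalogs split channels and marginalize exactly", {
  one <- data.frame(sample = "T1", chrom = "c", pos = 5, ref = "C", alt = "A",
                    context5 = "A", context3 = "A", strand = "coding")
  m <- build_stranded_catalog(one)
  expect_equal(m["A[C>A]A|+", "T1"], 1L)
  expect_equal(sum(m), 1)

  cfg <- simulation_config(n_patients = 2, mutations_per_tumor = 400, seed = 11)
  post <- generate_paired_cohort(cfg)$post
  assigned <- post[!is.na(post$strand), ]
  m192 <- build_stranded_catalog(assigned)
  m96 <- build_catalog(assigned)
  expect_equal(unname(collapse_stranded(m192)), unname(m96),
               ignore_attr = TRUE)

  unassigned <- post
  unassigned$strand <- NA_character_
  expect_error(build_stranded_catalog(unassigned), "strand-assigned")
})

test_that("context frequencies collapse windows onto pyrimidine labels", {
  ref1 <- Biostrings::DNAStringSet(c(w = "ACA"))
  f1 <- compute_context_frequencies(ref1)
  expect_equal(unname(f1["ACA"]), 1)
  expect_equal(sum(f1), 1)

  # "ACAC": windows ACA (pyrimidine center) and CAC (purine center -> GTG)
  ref2 <- Biostrings::DNAStringSet(c(w = "ACAC"))
  f2 <- compute_context_frequencies(ref2)
  expect_equal(unname(f2["ACA"]), 0.5)
  expect_equal(unname(f2["GTG"]), 0.5)

  # uniform random sequence: all 32 contexts near the 1/32 expectation
  big <- withr::with_seed(7, paste(sample(c("A", "C", "G", "T"), 1e6,
                                          replace = TRUE), collapse = ""))
  f3 <- compute_context_frequencies(Biostrings::DNAStringSet(c(w = big)))
  # overlapping windows are dependent: each base sits in up to three
  # windows, bounding the variance inflation at 3x the multinomial value
  se <- sqrt(3 * (1 / 32) * (31 / 32) / (1e6 - 2))
  expect_true(all(abs(f3 - 1 / 32) < 3 * se))

  expect_error(compute_context_frequencies(Biostrings::DNAStringSet(c(w = "AC"))),
               "countable")
})

test_that("territory frequencies take edge flanks from the reference", {
  ref <- Biostrings::DNAStringSet(c(c1 = "TTACGTT"))
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(start = 3, end = 5))
  f <- compute_context_frequencies(ref, gr)
  # centers 3..5: windows TAC, ACG, CGT; TAC -> GTA and CGT -> ACG
  # (purine centers recorded under their reverse complement)
  expect_equal(unname(f["GTA"]), 1 / 3)
  expect_equal(unname(f["ACG"]), 2 / 3)
})

test_that("detection power matches the exact binomial and is monotone", {
  expect_equal(detection_power(0, 0.5), 0)
  expect_equal(detection_power(1000, 0.5), 1, tolerance = 1e-9)
  exact <- 1 - sum(vapply(0:2, function(k) {
    choose(30, k) * 0.1^k * 0.9^(30 - k)
  }, numeric(1)))
  expect_equal(detection_power(30, 0.1), exact, tolerance = 1e-12)

  withr::with_seed(5, {
    depths <- sort(sample(0:200, 30))
    vafs <- sort(runif(30))
    expect_true(all(diff(detection_power(depths, 0.1)) >= 0))
    expect_true(all(diff(detection_power(100, vafs)) >= 0))
  })
  # exact enumeration oracle for depth <= 50
  for (d in c(5, 17, 50)) {
    for (v in c(0.05, 0.3)) {
      oracle <- sum(vapply(3:d, function(k) {
        choose(d, k) * v^k * (1 - v)^(d - k)
      }, numeric(1)))
      expect_equal(detection_power(d, v), oracle, tolerance = 1e-10)
    }
  }
})

test_that("paired classification applies the detection-power rule", {
  pre <- data.frame(patient = "P1", chrom = "c", pos = c(1, 2, 3),
                    sample = "P1_pre")
  post <- data.frame(patient = "P1", chrom = "c", pos = 1, sample = "P1_post")
  # pos 2: powered in post (depth 200, evaf .25); pos 3: unpowered (depth 4)
  sites <- data.frame(patient = "P1", chrom = "c", pos = c(1, 2, 3),
                      pre_depth = 100, post_depth = c(100, 200, 4),
                      pre_evaf = 0.25, post_evaf = 0.25)
  cls <- classify_shared_private(pre, post, sites)
  expect_equal(cls$timing[cls$pos == 1], "shared")
  expect_equal(cls$timing[cls$pos == 2], "pre_only")
  expect_equal(cls$timing[cls$pos == 3], "unpowered")

  bad_post <- data.frame(patient = "P2", chrom = "c", pos = 1,
                         sample = "P2_post")
  expect_error(classify_shared_private(pre, bad_post, sites), "pairing")
})

test_that("mutation readers handle TSV and VCF inputs", {
  skip_if_not_installed("vcfR")
  v <- read_mutations_vcf(extdata("synthetic_calls.vcf"), "T1")
  expect_equal(attr(v, "qc")$n_non_snv, 1)  # the planted insertion
  expect_equal(nrow(v), 6)
  expect_true(all(v$ref %in% c("A", "C", "G", "T")))
})

test_that("catalog and signature tables round-trip through TSV", {
  cfg <- simulation_config(n_patients = 2, mutations_per_tumor = 200, seed = 2)
  post <- generate_paired_cohort(cfg)$post
  m <- build_catalog(post)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(m, tf)
  expect_equal(read_catalog(tf), m, ignore_attr = TRUE)

  W <- generate_signatures(3, seed = 4)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_signatures(W, tf2)
  expect_equal(read_signatures(tf2), W, tolerance = 1e-12)

  bed <- read_territory(extdata("synthetic_territory.bed"))
  expect_equal(GenomicRanges::start(bed)[1], 10)  # 0-based BED -> 1-based
  expect_equal(GenomicRanges::end(bed)[1], 59)
})
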