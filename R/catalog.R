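#' Extract trinucleotide contexts from a reference sequence
#'
#' Looks up the reference-strand bases flanking each SNV and fills the
#' `context5`/`context3` columns. Records are excluded (and counted in the
#' `"qc"` attribute) when the stated reference allele does not match the
#' reference sequence, when the position is at a contig edge so a flank is
#' missing, or when the context contains an ambiguity code.
#'
#' @param mut Mutation data.frame with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param reference A [Biostrings::DNAStringSet] named by contig.
#' @return `mut` with `context5`/`context3` columns; attribute `"qc"` counts
#'   `n_ref_mismatch`, `n_edge`, `n_ambiguous`, `n_bad_chrom`.
#' @export
extract_context <- function(mut, reference) {
  stopifnot(is.data.frame(mut))
  n <- nrow(mut)
  ctx5 <- rep(NA_character_, n)
  ctxc <- rep(NA_character_, n)
  ctx3 <- rep(NA_character_, n)
  bad_chrom <- !(mut$chrom %in% names(reference))
  edge <- rep(FALSE, n)
  for (ch in unique(mut$chrom[!bad_chrom])) {
    i <- which(mut$chrom == ch)
    len <- length(reference[[ch]])
    e <- mut$pos[i] < 2 | mut$pos[i] > len - 1
    edge[i[e]] <- TRUE
    ok <- i[!e]
    if (length(ok) > 0) {
      v <- Biostrings::Views(reference[[ch]], start = mut$pos[ok] - 1L,
                             end = mut$pos[ok] + 1L)
      s <- as.character(v)
      ctx5[ok] <- substr(s, 1, 1)
      ctxc[ok] <- substr(s, 2, 2)
      ctx3[ok] <- substr(s, 3, 3)
    }
  }
  mismatch <- !bad_chrom & !edge & !is.na(ctxc) & ctxc != mut$ref
  ambiguous <- !bad_chrom & !edge & !mismatch &
    (!(ctx5 %in% BASES) | !(ctx3 %in% BASES))
  keep <- !bad_chrom & !edge & !mismatch & !ambiguous
  qc <- list(n_input = n,
             n_bad_chrom = sum(bad_chrom),
             n_edge = sum(edge),
             n_ref_mismatch = sum(mismatch),
             n_ambiguous = sum(ambiguous))
  if (qc$n_ref_mismatch > 0) {
    warning(qc$n_ref_mismatch,
            " record(s) whose ref allele does not match the reference were excluded")
  }
  out <- mut[keep, , drop = FALSE]
  out$context5 <- ctx5[keep]
  out$context3 <- ctx3[keep]
  attr(out, "qc") <- qc
  out
}

#' Assign 96-channel indices to mutation records
#'
#' Requires `context5`/`context3` columns (see [extract_context()]); records
#' with ambiguous context bases are excluded and counted.
#'
#' @param mut Mutation data.frame with `ref`, `alt`, `context5`, `context3`.
#' @return `mut` with `channel` (1--96) and `channel_label` columns.
#' @export
mutation_channels <- function(mut) {
  if (!all(c("context5", "context3") %in% names(mut))) {
    stop("mutations lack context columns; run extract_context() with a reference first")
  }
  ok <- mut$ref %in% BASES & mut$alt %in% BASES &
    mut$context5 %in% BASES & mut$context3 %in% BASES
  n_ambiguous <- sum(!ok)
  mut <- mut[ok, , drop = FALSE]
  if (nrow(mut) > 0) {
    cc <- collapse_to_pyrimidine(mut$ref, mut$alt, mut$context5, mut$context3)
    mut$channel <- cc$channel
    mut$channel_label <- cc$label
  } else {
    mut$channel <- integer(0)
    mut$channel_label <- character(0)
  }
  attr(mut, "qc") <- list(n_ambiguous = n_ambiguous)
  mut
}

#' Build a 96-channel mutation catalog
#'
#' Counts SNVs per channel per sample. Column sums equal the number of
#' retained SNVs per sample.
#'
#' @param mut Mutation data.frame with `sample` and either `channel` or
#'   `context5`/`context3` columns (channels derived if absent).
#' @param reference Optional [Biostrings::DNAStringSet]; used to fill
#'   contexts when missing.
#' @param samples Optional character vector fixing the column order (samples
#'   with no mutations get all-zero columns).
#' @return Integer matrix 96 x samples with channel-label rownames;
#'   attribute `"qc"` carries exclusion counts from context assignment.
#' @export
build_catalog <- function(mut, reference = NULL, samples = NULL) {
  if (!("channel" %in% names(mut))) {
    if (!all(c("context5", "context3") %in% names(mut))) {
      if (is.null(reference)) {
        stop("mutations lack contexts and no reference was given")
      }
      mut <- extract_context(mut, reference)
    }
    mut <- mutation_channels(mut)
  }
  if (is.null(samples)) samples <- sort(unique(as.character(mut$sample)))
  counts <- table(factor(mut$channel, levels = seq_len(96)),
                  factor(as.character(mut$sample), levels = samples))
  m <- matrix(as.integer(counts), nrow = 96,
              dimnames = list(channel_labels(), samples))
  attr(m, "qc") <- attr(mut, "qc")
  m
}

#' Build a transcription-stranded 192-channel catalog
#'
#' Splits each pyrimidine channel into coding(+) and noncoding(-)
#' sub-channels using the per-record `strand` column (`"coding"`/`"+"` or
#' `"noncoding"`/`"-"`). Records without a strand assignment are excluded
#' and counted; collapsing the result with [collapse_stranded()] equals
#' [build_catalog()] on the retained records.
#'
#' @inheritParams build_catalog
#' @return Integer matrix 192 x samples; attribute `"qc"` includes
#'   `n_unassigned`.
#' @export
build_stranded_catalog <- function(mut, reference = NULL, samples = NULL) {
  if (!("channel" %in% names(mut))) {
    if (!all(c("context5", "context3") %in% names(mut))) {
      if (is.null(reference)) {
        stop("mutations lack contexts and no reference was given")
      }
      mut <- extract_context(mut, reference)
    }
    mut <- mutation_channels(mut)
  }
  if (!("strand" %in% names(mut))) stop("mutations lack a strand column")
  strand <- as.character(mut$strand)
  strand[strand == "+"] <- "coding"
  strand[strand == "-"] <- "noncoding"
  assigned <- !is.na(strand) & strand %in% c("coding", "noncoding")
  n_unassigned <- sum(!assigned)
  mut <- mut[assigned, , drop = FALSE]
  strand <- strand[assigned]
  if (nrow(mut) == 0) stop("no strand-assigned records; cannot build a stranded catalog")
  if (is.null(samples)) samples <- sort(unique(as.character(mut$sample)))
  ch192 <- stranded_channel(mut$channel, strand)
  counts <- table(factor(ch192, levels = seq_len(192)),
                  factor(as.character(mut$sample), levels = samples))
  m <- matrix(as.integer(counts), nrow = 192,
              dimnames = list(channel_labels_192(), samples))
  attr(m, "qc") <- c(attr(mut, "qc"), list(n_unassigned = n_unassigned))
  m
}

#' Trinucleotide context frequencies of a territory
#'
#' Counts every trinucleotide window whose center base lies in the territory
#' (whole contigs when `territory` is `NULL`), takes flanking bases from the
#' reference even when they fall outside an interval, collapses
#' purine-centered windows onto their reverse complement, and normalizes.
#' Windows at contig edges (missing a flank) and windows containing
#' ambiguity codes are skipped.
#'
#' @param reference A [Biostrings::DNAStringSet].
#' @param territory Optional [GenomicRanges::GRanges] of 1-based intervals
#'   (e.g. from [read_territory()]).
#' @param name Territory name stored in the `"territory_name"` attribute.
#' @return Named numeric vector over the 32 pyrimidine-centered contexts,
#'   summing to 1.
#' @export
compute_context_frequencies <- function(reference, territory = NULL,
                                        name = "territory") {
  counts64 <- integer(64)
  names(counts64) <- Biostrings::mkAllStrings(BASES, 3)
  if (is.null(territory)) {
    for (i in seq_along(reference)) {
      tf <- Biostrings::trinucleotideFrequency(reference[[i]])
      counts64 <- counts64 + tf[names(counts64)]
    }
  } else {
    territory <- GenomicRanges::reduce(territory)
    chroms <- as.character(GenomicRanges::seqnames(territory))
    starts <- GenomicRanges::start(territory)
    ends <- GenomicRanges::end(territory)
    for (j in seq_along(territory)) {
      ch <- chroms[j]
      if (!(ch %in% names(reference))) {
        stop("territory contig not in reference: ", ch)
      }
      len <- length(reference[[ch]])
      s <- max(starts[j] - 1L, 1L)
      e <- min(ends[j] + 1L, len)
      if (e - s + 1L < 3L) next
      sub <- Biostrings::subseq(reference[[ch]], s, e)
      tf <- Biostrings::trinucleotideFrequency(sub)
      counts64 <- counts64 + tf[names(counts64)]
    }
  }
  ctx <- pyrimidine_contexts()
  counts32 <- counts64[ctx] + counts64[revcomp(ctx)]
  names(counts32) <- ctx
  total <- sum(counts32)
  if (total == 0) stop("territory contains no countable trinucleotide windows")
  freq <- counts32 / total
  attr(freq, "territory_name") <- name
  freq
}

#' Detection power under a binomial read-count model
#'
#' Probability that a variant present at expected allele fraction
#' `expected_vaf` yields at least `min_alt_reads` supporting reads among
#' `depth` reads, with alt reads binomial. A symmetric per-read error rate
#' shifts the effective success probability to
#' `vaf * (1 - error_rate) + (1 - vaf) * error_rate`.
#'
#' @param depth Integer read depth(s).
#' @param expected_vaf Expected variant allele fraction(s) in `[0, 1]`
#'   (typically purity x CCF x multiplicity / local copy number, or
#'   purity / 2 for a heterozygous diploid site).
#' @param min_alt_reads Minimum supporting reads for a call (default 3).
#' @param error_rate Per-read error rate (default 0).
#' @return Numeric vector of powers in `[0, 1]`, monotone non-decreasing in
#'   both `depth` and `expected_vaf`.
#' @export
detection_power <- function(depth, expected_vaf, min_alt_reads = 3,
                            error_rate = 0) {
  stopifnot(all(depth >= 0), all(expected_vaf >= 0 & expected_vaf <= 1),
            min_alt_reads >= 1)
  p <- expected_vaf * (1 - error_rate) + (1 - expected_vaf) * error_rate
  stats::pbinom(min_alt_reads - 1, depth, p, lower.tail = FALSE)
}

#' Detection power model parameters
#'
#' @param min_alt_reads Minimum supporting reads for detection (default 3,
#'   the usual supporting-read filter for somatic calls).
#' @param error_rate Per-read error rate (default 0).
#' @param power_threshold Power required to treat an absence as informative
#'   (default 0.8).
#' @return A `power_model` list.
#' @export
power_model <- function(min_alt_reads = 3, error_rate = 0,
                        power_threshold = 0.8) {
  stopifnot(min_alt_reads >= 1, power_threshold > 0, power_threshold < 1,
            error_rate >= 0, error_rate < 0.5)
  structure(list(min_alt_reads = min_alt_reads, error_rate = error_rate,
                 power_threshold = power_threshold), class = "power_model")
}

.site_key <- function(df) paste(df$patient, df$chrom, df$pos, sep = ":")

#' Classify mutations of paired tumors as shared, private, or unpowered
#'
#' Pre/post comparisons are only meaningful at sites that were detected, or
#' adequately powered for detection, in both tumors. A site detected in both
#' tumors is `shared`; a site detected in one tumor is `pre_only` /
#' `post_only` when the other tumor had detection power at or above the
#' model's threshold, and `unpowered` (excluded from pre/post load
#' comparisons) otherwise.
#'
#' @param pre,post Mutation data.frames of the detected mutations in the
#'   pre- and post-treatment tumors, with `patient`, `chrom`, `pos`.
#' @param sites Per-site coverage data.frame with `patient`, `chrom`, `pos`,
#'   `pre_depth`, `post_depth`, `pre_evaf`, `post_evaf` (expected VAF of the
#'   variant in each tumor). Sites detected somewhere but missing here are
#'   treated as unpowered.
#' @param model A [power_model()].
#' @return Data.frame with one row per site in the union: `patient`,
#'   `chrom`, `pos`, `detected_pre`, `detected_post`, `power_pre`,
#'   `power_post`, `timing` in `{shared, pre_only, post_only, unpowered}`.
#' @export
classify_shared_private <- function(pre, post, sites, model = power_model()) {
  for (nm in c("pre", "post")) {
    df <- get(nm)
    if (!("patient" %in% names(df))) {
      stop("'", nm, "' table lacks a patient column; cannot pair tumors")
    }
  }
  if (!setequal(unique(pre$patient), unique(post$patient))) {
    stop("pre and post tables contain different patient ids; pairing failed")
  }
  key_pre <- unique(.site_key(pre))
  key_post <- unique(.site_key(post))
  all_keys <- union(key_pre, key_post)
  parts <- do.call(rbind, strsplit(all_keys, ":", fixed = TRUE))
  out <- data.frame(patient = parts[, 1], chrom = parts[, 2],
                    pos = as.integer(parts[, 3]),
                    detected_pre = all_keys %in% key_pre,
                    detected_post = all_keys %in% key_post,
                    stringsAsFactors = FALSE)
  skey <- .site_key(sites)
  i <- match(all_keys, skey)
  out$power_pre <- ifelse(is.na(i), NA_real_,
                          detection_power(sites$pre_depth[i], sites$pre_evaf[i],
                                          model$min_alt_reads, model$error_rate))
  out$power_post <- ifelse(is.na(i), NA_real_,
                           detection_power(sites$post_depth[i], sites$post_evaf[i],
                                           model$min_alt_reads, model$error_rate))
  thr <- model$power_threshold
  timing <- rep("unpowered", nrow(out))
  timing[out$detected_pre & out$detected_post] <- "shared"
  timing[out$detected_pre & !out$detected_post &
           !is.na(out$power_post) & out$power_post >= thr] <- "pre_only"
  timing[!out$detected_pre & out$detected_post &
           !is.na(out$power_pre) & out$power_pre >= thr] <- "post_only"
  out$timing <- timing
  out
}

#' Extract mutations private to the post-treatment tumor
#'
#' Returns the rows of `post` at sites classified `post_only` -- detected
#' only post-treatment despite adequate power pre-treatment. This set,
#' enriched for treatment-induced mutations, is the input to
#' validation-style signature discovery.
#'
#' @inheritParams classify_shared_private
#' @return Subset of `post`; warns when empty.
#' @export
extract_post_only <- function(pre, post, sites, model = power_model()) {
  cls <- classify_shared_private(pre, post, sites, model)
  keys <- .site_key(cls[cls$timing == "post_only", , drop = FALSE])
  out <- post[.site_key(post) %in% keys, , drop = FALSE]
  if (nrow(out) == 0) warning("no post-only mutations found")
  out
}
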