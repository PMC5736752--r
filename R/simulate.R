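#' Generate random mutational signatures
#'
#' Draws `K` signatures as symmetric Dirichlet vectors over the 96
#' channels, rejecting draws whose cosine similarity to an already accepted
#' signature reaches `max_cosine` -- well-separated signatures keep planted
#' truth identifiable in recovery experiments.
#'
#' @param K Number of signatures.
#' @param concentration Dirichlet concentration (default 0.5; smaller gives
#'   spikier signatures).
#' @param seed Seed.
#' @param max_cosine Pairwise cosine similarity bound (default 0.8).
#' @param max_draws Total draws allowed before giving up (default 1000).
#' @return 96 x K matrix with columns summing to 1, named `S1..SK`.
#' @export
generate_signatures <- function(K, concentration = 0.5, seed = 1,
                                max_cosine = 0.8, max_draws = 1000) {
  stopifnot(K >= 1, concentration > 0)
  withr::with_seed(seed, {
    sigs <- matrix(NA_real_, 96, K)
    accepted <- 0L
    for (d in seq_len(max_draws)) {
      cand <- stats::rgamma(96, concentration)
      cand <- cand / sum(cand)
      ok <- TRUE
      if (accepted > 0) {
        for (j in seq_len(accepted)) {
          if (cosine_similarity(cand, sigs[, j]) >= max_cosine) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        accepted <- accepted + 1L
        sigs[, accepted] <- cand
        if (accepted == K) break
      }
    }
    if (accepted < K) {
      stop("could not draw ", K, " signatures with pairwise cosine < ",
           max_cosine, " in ", max_draws, " draws; lower the concentration")
    }
    rownames(sigs) <- channel_labels()
    colnames(sigs) <- paste0("S", seq_len(K))
    sigs
  })
}

#' Configuration of a synthetic paired pre/post cohort
#'
#' Defaults emulate a cohort of matched pre-/post-chemotherapy exome pairs:
#' 30 patients with 2000 detected-scale mutations per tumor; three
#' background signatures with per-patient Dirichlet exposures; a treatment
#' signature confined to post-private subclonal mutations at 15% of the
#' post-treatment burden; a clonal trunk carrying most shared mutations
#' (shared subclonal mutations are rare); per-site depths from a negative
#' binomial (mean 150, dispersion 5) and purity-driven allele fractions so
#' low-CCF mutations can escape detection; and a transcriptional strand
#' bias (noncoding:coding = 3) for the treatment signature in the C>A,
#' C>T, T>A and T>C classes.
#'
#' @param n_patients Number of patients.
#' @param mutations_per_tumor True mutations per tumor (pre and post).
#' @param n_signatures Number of background signatures.
#' @param signatures Optional 96 x (n_signatures + 1) matrix (last column
#'   is the treatment signature); generated when `NULL`.
#' @param signature_concentration Dirichlet concentration for generated
#'   signatures.
#' @param exposure_concentration Dirichlet concentration of per-patient
#'   background exposures.
#' @param treatment_fraction Cohort-mean fraction of post-treatment
#'   mutations drawn from the treatment signature (all post-private
#'   subclonal).
#' @param treatment_fraction_spread Half-width of the per-patient burden:
#'   each patient's treatment fraction is Uniform(mean - spread,
#'   mean + spread), truncated at 0 and at the private-mutation budget
#'   (treatment-signature activity varies widely between tumors; a
#'   constant share would be unrealistically homogeneous).
#' @param shared_fraction Fraction of each tumor's mutations in shared
#'   subclones.
#' @param clonal_fraction Fraction of shared mutations on the clonal trunk.
#' @param n_shared_subclones Shared subclones including the trunk.
#' @param n_pre_private,n_post_private Private subclones per side.
#' @param subclonal_ccf_range CCF range for subclonal populations.
#' @param purity_range Tumor purity range.
#' @param depth_mean,depth_dispersion Negative-binomial depth model.
#' @param min_alt_reads Supporting reads required for detection.
#' @param strand_bias Optional (n_signatures + 1) x 6 matrix of
#'   noncoding:coding ratios (rows = signatures incl. treatment, columns =
#'   [sbs_classes()]); default 1 everywhere except the treatment rows
#'   named above.
#' @param strand_assigned_fraction Fraction of mutations with a transcript
#'   strand assignment.
#' @param ccf_noise Beta noise level for emitted CCFs (0 = exact truth).
#' @param seed Mandatory seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 30, mutations_per_tumor = 2000,
                              n_signatures = 3, signatures = NULL,
                              signature_concentration = 0.5,
                              exposure_concentration = 1,
                              treatment_fraction = 0.15,
                              treatment_fraction_spread = 0.10,
                              shared_fraction = 0.75,
                              clonal_fraction = 0.95,
                              n_shared_subclones = 2,
                              n_pre_private = 1, n_post_private = 1,
                              subclonal_ccf_range = c(0.15, 0.7),
                              purity_range = c(0.5, 0.9),
                              depth_mean = 150, depth_dispersion = 5,
                              min_alt_reads = 3,
                              strand_bias = NULL,
                              strand_assigned_fraction = 0.8,
                              ccf_noise = 0,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(treatment_fraction >= 0, treatment_fraction <= 1,
            shared_fraction > 0, shared_fraction < 1,
            clonal_fraction >= 0, clonal_fraction <= 1,
            n_shared_subclones >= 1, n_pre_private >= 1, n_post_private >= 1,
            strand_assigned_fraction >= 0, strand_assigned_fraction <= 1)
  n_private <- mutations_per_tumor - round(shared_fraction * mutations_per_tumor)
  if (round(treatment_fraction * mutations_per_tumor) > n_private) {
    stop("treatment_fraction exceeds the post-private mutation budget")
  }
  stopifnot(treatment_fraction_spread >= 0)
  K <- n_signatures
  if (!is.null(signatures)) {
    signatures <- as.matrix(signatures)
    stopifnot(nrow(signatures) == 96, ncol(signatures) == K + 1)
  }
  if (is.null(strand_bias)) {
    strand_bias <- matrix(1, K + 1, 6,
                          dimnames = list(NULL, sbs_classes()))
    strand_bias[K + 1, c("C>A", "C>T", "T>A", "T>C")] <- 3
  }
  stopifnot(nrow(strand_bias) == K + 1, ncol(strand_bias) == 6)
  structure(list(n_patients = n_patients,
                 mutations_per_tumor = mutations_per_tumor,
                 n_signatures = n_signatures, signatures = signatures,
                 signature_concentration = signature_concentration,
                 exposure_concentration = exposure_concentration,
                 treatment_fraction = treatment_fraction,
                 treatment_fraction_spread = treatment_fraction_spread,
                 shared_fraction = shared_fraction,
                 clonal_fraction = clonal_fraction,
                 n_shared_subclones = n_shared_subclones,
                 n_pre_private = n_pre_private,
                 n_post_private = n_post_private,
                 subclonal_ccf_range = subclonal_ccf_range,
                 purity_range = purity_range,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 min_alt_reads = min_alt_reads,
                 strand_bias = strand_bias,
                 strand_assigned_fraction = strand_assigned_fraction,
                 ccf_noise = ccf_noise,
                 seed = seed),
            class = "simulation_config")
}

.channel_decode_table <- function() {
  cls <- sbs_classes()
  i <- seq_len(96)
  cls_i <- (i - 1L) %/% 16L + 1L
  rem <- (i - 1L) %% 16L
  data.frame(ref = substr(cls[cls_i], 1, 1),
             alt = substr(cls[cls_i], 3, 3),
             f5 = BASES[rem %/% 4L + 1L],
             f3 = BASES[rem %% 4L + 1L],
             stringsAsFactors = FALSE)
}

.sample_channels <- function(sig_idx, W) {
  out <- integer(length(sig_idx))
  for (k in unique(sig_idx)) {
    i <- which(sig_idx == k)
    out[i] <- sample.int(96, length(i), replace = TRUE, prob = W[, k])
  }
  out
}

.resample <- function(x, n) {
  # sample() treats a length-1 numeric as 1:x; this never does
  x[sample.int(length(x), n, replace = TRUE)]
}

.noisy_ccf <- function(ccf, noise) {
  if (noise <= 0) return(ccf)
  conc <- 1 / noise
  out <- ccf
  sub <- ccf > 0 & ccf < 1
  out[sub] <- stats::rbeta(sum(sub), ccf[sub] * conc, (1 - ccf[sub]) * conc)
  out
}

#' Generate a paired pre/post cohort with planted truth
#'
#' Simulates the full data structure the analysis chain consumes: per
#' patient, a clonal trunk plus shared and private subclones with pre/post
#' CCFs; mutations assigned to subclones (fixing CCF, clonality and
#' timing); channels drawn from the planted signature mixture, with the
#' treatment signature drawn only for post-private subclonal mutations;
#' reference-strand allele/context representation (half the mutations
#' emitted on the purine strand); transcript strand classes drawn with the
#' configured per-class bias; and per-site depths and alt read counts in
#' both tumors so the detection-power filter is exercised. The emitted
#' `pre`/`post` tables contain only detected mutations (at least
#' `min_alt_reads` supporting reads); the truth bundle retains everything.
#'
#' @param config A [simulation_config()].
#' @return List: `pre`, `post` (MAF-like detected-mutation tables), `sites`
#'   (per-site depths and expected VAFs for [classify_shared_private()]),
#'   and `truth` with `signatures` (96 x (K+1), last column `TRT`),
#'   `exposures`, `purity`, `subclones`, `mutations` (complete truth
#'   table), and `config`.
#' @export
generate_paired_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .generate_paired_cohort_impl(config))
}

.generate_paired_cohort_impl <- function(cfg) {
  K <- cfg$n_signatures
  W <- cfg$signatures
  if (is.null(W)) {
    W <- generate_signatures(K + 1, cfg$signature_concentration,
                             seed = sample.int(2^30, 1))
  }
  colnames(W) <- c(paste0("BG", seq_len(K)), "TRT")
  decode <- .channel_decode_table()
  ccf_lo <- cfg$subclonal_ccf_range[1]; ccf_hi <- cfg$subclonal_ccf_range[2]
  N <- cfg$mutations_per_tumor
  n_shared_mut <- round(cfg$shared_fraction * N)
  n_clonal <- round(cfg$clonal_fraction * n_shared_mut)
  n_shared_sub <- n_shared_mut - n_clonal
  n_private <- N - n_shared_mut

  exposures <- matrix(stats::rgamma(cfg$n_patients * K,
                                    cfg$exposure_concentration),
                      cfg$n_patients, K)
  exposures <- exposures / rowSums(exposures)
  colnames(exposures) <- paste0("BG", seq_len(K))

  all_mut <- vector("list", cfg$n_patients)
  all_sub <- vector("list", cfg$n_patients)
  purity <- data.frame(patient = character(0), pre = numeric(0),
                       post = numeric(0))
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    f_trt <- stats::runif(1, cfg$treatment_fraction - cfg$treatment_fraction_spread,
                          cfg$treatment_fraction + cfg$treatment_fraction_spread)
    n_trt <- min(max(round(f_trt * N), 0L), n_private)
    pur_pre <- stats::runif(1, cfg$purity_range[1], cfg$purity_range[2])
    pur_post <- stats::runif(1, cfg$purity_range[1], cfg$purity_range[2])
    purity <- rbind(purity, data.frame(patient = pid, pre = pur_pre,
                                       post = pur_post))
    n_ss <- cfg$n_shared_subclones - 1L  # shared subclonal (non-trunk)
    sub <- data.frame(
      patient = pid,
      subclone = seq_len(1L + n_ss + cfg$n_pre_private + cfg$n_post_private),
      type = c("trunk", rep("shared", n_ss),
               rep("pre_private", cfg$n_pre_private),
               rep("post_private", cfg$n_post_private)),
      stringsAsFactors = FALSE)
    sub$pre_ccf <- c(1, stats::runif(n_ss, ccf_lo, ccf_hi),
                     stats::runif(cfg$n_pre_private, ccf_lo, ccf_hi),
                     rep(0, cfg$n_post_private))
    sub$post_ccf <- c(1, stats::runif(n_ss, ccf_lo, ccf_hi),
                      rep(0, cfg$n_pre_private),
                      stats::runif(cfg$n_post_private, ccf_lo, ccf_hi))

    # subclone assignment per mutation
    shared_ids <- c(rep(1L, n_clonal),
                    if (n_ss > 0 && n_shared_sub > 0) {
                      .resample(sub$subclone[sub$type == "shared"],
                                n_shared_sub)
                    } else rep(1L, n_shared_sub))
    pre_ids <- .resample(sub$subclone[sub$type == "pre_private"], n_private)
    post_ids <- .resample(sub$subclone[sub$type == "post_private"], n_private)
    subclone <- c(shared_ids, pre_ids, post_ids)
    timing <- rep(c("shared", "pre_only", "post_only"),
                  c(n_shared_mut, n_private, n_private))

    # signature per mutation: treatment only in post-private subclonal
    n_total <- length(subclone)
    sig_idx <- sample.int(K, n_total, replace = TRUE, prob = exposures[p, ])
    post_rows <- which(timing == "post_only")
    trt_rows <- post_rows[sample.int(length(post_rows), n_trt)]
    sig_idx[trt_rows] <- K + 1L

    channel <- .sample_channels(sig_idx, W)
    cls <- .class_of_channel(channel)

    # reference-strand representation: half on the purine strand
    flip <- stats::runif(n_total) < 0.5
    ref <- ifelse(flip, chartr("ACGT", "TGCA", decode$ref[channel]),
                  decode$ref[channel])
    alt <- ifelse(flip, chartr("ACGT", "TGCA", decode$alt[channel]),
                  decode$alt[channel])
    context5 <- ifelse(flip, chartr("ACGT", "TGCA", decode$f3[channel]),
                       decode$f5[channel])
    context3 <- ifelse(flip, chartr("ACGT", "TGCA", decode$f5[channel]),
                       decode$f3[channel])

    # transcript strand class with configured noncoding:coding bias
    assigned <- stats::runif(n_total) < cfg$strand_assigned_fraction
    ratio <- cfg$strand_bias[cbind(sig_idx, match(cls, sbs_classes()))]
    p_noncoding <- ratio / (1 + ratio)
    strand <- ifelse(assigned,
                     ifelse(stats::runif(n_total) < p_noncoding,
                            "noncoding", "coding"),
                     NA_character_)

    si <- match(subclone, sub$subclone)
    ccf_pre <- sub$pre_ccf[si]
    ccf_post <- sub$post_ccf[si]
    pos <- sample.int(3e7, n_total)

    pre_depth <- stats::rnbinom(n_total, mu = cfg$depth_mean,
                                size = cfg$depth_dispersion)
    post_depth <- stats::rnbinom(n_total, mu = cfg$depth_mean,
                                 size = cfg$depth_dispersion)
    # expected VAF of the variant in each tumor; for a tumor where the
    # subclone is absent, the power-relevant VAF uses the other tumor's CCF
    pre_evaf <- pur_pre * ifelse(ccf_pre > 0, ccf_pre, ccf_post) / 2
    post_evaf <- pur_post * ifelse(ccf_post > 0, ccf_post, ccf_pre) / 2
    pre_alt <- ifelse(ccf_pre > 0,
                      stats::rbinom(n_total, pre_depth, pur_pre * ccf_pre / 2),
                      0L)
    post_alt <- ifelse(ccf_post > 0,
                       stats::rbinom(n_total, post_depth,
                                     pur_post * ccf_post / 2),
                       0L)

    all_mut[[p]] <- data.frame(
      patient = pid, chrom = "chr1", pos = pos, ref = ref, alt = alt,
      context5 = context5, context3 = context3, channel = channel,
      snv_class = cls, signature = colnames(W)[sig_idx], subclone = subclone,
      timing = timing, ccf_pre = ccf_pre, ccf_post = ccf_post,
      clonality_pre = ccf_clonality(ifelse(ccf_pre > 0, ccf_pre, NA)),
      clonality_post = ccf_clonality(ifelse(ccf_post > 0, ccf_post, NA)),
      strand = strand, pre_depth = pre_depth, post_depth = post_depth,
      pre_evaf = pre_evaf, post_evaf = post_evaf,
      pre_alt = pre_alt, post_alt = post_alt,
      detected_pre = ccf_pre > 0 & pre_alt >= cfg$min_alt_reads,
      detected_post = ccf_post > 0 & post_alt >= cfg$min_alt_reads,
      stringsAsFactors = FALSE)
    all_sub[[p]] <- sub
  }
  mut <- do.call(rbind, all_mut)
  subclones <- do.call(rbind, all_sub)

  emit <- function(side) {
    det <- mut[mut[[paste0("detected_", side)]], , drop = FALSE]
    ccf <- .noisy_ccf(det[[paste0("ccf_", side)]], cfg$ccf_noise)
    data.frame(sample = paste0(det$patient, "_", side),
               patient = det$patient, chrom = det$chrom, pos = det$pos,
               ref = det$ref, alt = det$alt,
               context5 = det$context5, context3 = det$context3,
               ccf = ccf, subclone = det$subclone,
               clonality = det[[paste0("clonality_", side)]],
               strand = det$strand,
               t_depth = det[[paste0(side, "_depth")]],
               t_alt_count = det[[paste0(side, "_alt")]],
               stringsAsFactors = FALSE)
  }
  sites <- mut[, c("patient", "chrom", "pos", "pre_depth", "post_depth",
                   "pre_evaf", "post_evaf")]
  list(pre = emit("pre"), post = emit("post"), sites = sites,
       truth = list(signatures = W, exposures = exposures, purity = purity,
                    subclones = subclones, mutations = mut, config = cfg))
}
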