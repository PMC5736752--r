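#' Renormalize a signature between trinucleotide-frequency territories
#'
#' A signature measured in one territory (e.g. the chicken genome) is
#' mapped to another (e.g. the human exome) by scaling each channel by the
#' ratio of the target to source frequency of its trinucleotide context and
#' renormalizing to sum 1. The 32 pyrimidine-collapsed context frequencies
#' are applied uniformly to the three channels sharing each context. The
#' map is exactly invertible for strictly positive frequency tables.
#'
#' @param sig Numeric vector of length 96 (channel order as in
#'   [channel_labels()]).
#' @param source,target Context frequency tables from
#'   [compute_context_frequencies()] (named numeric over the 32 contexts).
#' @return Renormalized signature vector of length 96, summing to 1.
#' @export
renormalize_signature <- function(sig, source, target) {
  stopifnot(length(sig) == 96)
  ctx <- pyrimidine_contexts()
  if (!all(ctx %in% names(source)) || !all(ctx %in% names(target))) {
    stop("frequency tables must cover all 32 pyrimidine-centered contexts")
  }
  ch_ctx <- channel_context()
  src <- as.numeric(source[ch_ctx])
  tgt <- as.numeric(target[ch_ctx])
  if (any(src == 0 & sig > 0)) {
    stop("zero source frequency on a channel with nonzero signature mass")
  }
  out <- ifelse(sig > 0, sig * tgt / src, 0)
  s <- sum(out)
  if (s == 0) stop("renormalized signature has zero mass")
  out <- out / s
  names(out) <- channel_labels()
  out
}

#' Correlate activities of a candidate signature and a replacement spectrum
#'
#' Refits the catalog twice -- once with the original signature set, once
#' with the candidate signature's column replaced by `replacement` -- and
#' computes the Pearson correlation between the candidate's and the
#' replacement's inferred activities across samples. A high correlation
#' indicates the two spectra absorb the same mutations, i.e. describe the
#' same mutational process.
#'
#' @param catalog Channels x samples matrix.
#' @param signatures Channels x K matrix containing `candidate_name`.
#' @param candidate_name Column name of the candidate signature.
#' @param replacement Replacement channel distribution (length = channels,
#'   summing to 1).
#' @param config A [refit_config()] used for both refits.
#' @param candidate_activities Optional precomputed candidate activity
#'   vector (from refitting with the original set), to avoid repeating the
#'   first refit across many calls.
#' @return List: `r` (Pearson correlation, `NA` when undefined), `flag`
#'   (`"ok"`, `"constant_activity"`), `candidate_activity`,
#'   `replacement_activity`.
#' @export
substitute_and_correlate <- function(catalog, signatures, candidate_name,
                                     replacement, config = refit_config(),
                                     candidate_activities = NULL) {
  W <- as.matrix(signatures)
  if (!(candidate_name %in% colnames(W))) {
    stop("candidate signature '", candidate_name, "' not in signature set")
  }
  if (length(replacement) != nrow(W)) {
    stop("replacement length does not match channel count")
  }
  if (is.null(candidate_activities)) {
    fit0 <- infer_activities(catalog, W, config)
    candidate_activities <- fit0$activities[candidate_name, ]
  }
  W2 <- W
  W2[, candidate_name] <- replacement / sum(replacement)
  fit1 <- infer_activities(catalog, W2, config)
  replacement_activities <- fit1$activities[candidate_name, ]
  flag <- "ok"
  r <- NA_real_
  if (stats::sd(candidate_activities) == 0 ||
      stats::sd(replacement_activities) == 0) {
    flag <- "constant_activity"
  } else {
    r <- stats::cor(candidate_activities, replacement_activities)
  }
  list(r = r, flag = flag,
       candidate_activity = candidate_activities,
       replacement_activity = replacement_activities)
}

.draw_surrogates <- function(replacement, method, n, reference_panel, seed) {
  withr::with_seed(seed, {
    if (method == "permute_channels") {
      lapply(seq_len(n), function(i) {
        replacement[sample.int(length(replacement))]
      })
    } else {
      lapply(seq_len(n), function(i) {
        pair <- sample.int(ncol(reference_panel), 2)
        w <- stats::runif(1)
        s <- w * reference_panel[, pair[1]] +
          (1 - w) * reference_panel[, pair[2]]
        s / sum(s)
      })
    }
  })
}

#' Permutation null distribution for an activity correlation
#'
#' Assesses how often a correlation as strong as the observed
#' candidate-vs-replacement activity correlation arises by chance, by
#' rebuilding the replacement spectrum `n` times under one of two null
#' mechanisms and repeating the substitution refit:
#' `"permute_channels"` randomly permutes all 96 entries of the replacement
#' spectrum jointly; `"reference_combination"` draws `w * ref_a +
#' (1 - w) * ref_b` for two distinct reference signatures chosen uniformly
#' and `w ~ Uniform(0, 1)`, renormalized. The empirical p-value is the
#' proportion of null correlations at least as large as the observed one
#' (denominator `n`, no add-one correction).
#'
#' @inheritParams substitute_and_correlate
#' @param method `"permute_channels"` or `"reference_combination"`.
#' @param n Number of null draws (default 10000; below 100 a warning about
#'   p-value instability is issued).
#' @param reference_panel Channels x signatures matrix of at least two
#'   reference signatures; required for `"reference_combination"`.
#' @param seed Seed controlling the null draws (refit starts for draw `i`
#'   use `config$seed + i`).
#' @return List of class `null_distribution`: `method`, `values` (length
#'   `n`), `n`, `observed`, `empirical_p`, `seed`, `n_undefined` (null
#'   draws with undefined correlation, excluded from the proportion).
#' @export
permutation_null <- function(catalog, signatures, candidate_name, replacement,
                             method = c("permute_channels",
                                        "reference_combination"),
                             n = 10000, reference_panel = NULL,
                             config = refit_config(), seed = 1) {
  method <- match.arg(method)
  if (n < 100) warning("n < 100 null draws gives an unstable empirical p-value")
  if (method == "reference_combination") {
    if (is.null(reference_panel) || ncol(reference_panel) < 2) {
      stop("reference_combination requires a reference panel with >= 2 signatures")
    }
    reference_panel <- as.matrix(reference_panel)
  }
  W <- as.matrix(signatures)
  fit0 <- infer_activities(catalog, W, config)
  cand_act <- fit0$activities[candidate_name, ]
  obs <- substitute_and_correlate(catalog, W, candidate_name, replacement,
                                  config, candidate_activities = cand_act)
  surrogates <- .draw_surrogates(replacement, method, n, reference_panel, seed)
  values <- numeric(n)
  for (i in seq_len(n)) {
    surrogate <- surrogates[[i]]
    cfg <- config
    cfg$seed <- config$seed + i
    values[i] <- substitute_and_correlate(catalog, W, candidate_name,
                                          surrogate, cfg,
                                          candidate_activities = cand_act)$r
  }
  n_undef <- sum(is.na(values))
  structure(list(method = method, values = values, n = n, observed = obs$r,
                 empirical_p = mean(values >= obs$r, na.rm = TRUE),
                 seed = seed, n_undefined = n_undef,
                 observed_flag = obs$flag),
            class = "null_distribution")
}
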