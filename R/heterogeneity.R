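#' Proportion of subclonal mutations in one tumor
#'
#' @param clonality Character vector of per-mutation labels (`"clonal"`,
#'   `"subclonal"`, other values count as unknown and are excluded).
#' @return The subclonal proportion among labeled mutations; attribute
#'   `"n_unknown"` counts exclusions. Errors when no mutation is labeled.
#' @export
proportion_subclonal <- function(clonality) {
  known <- clonality %in% c("clonal", "subclonal")
  if (!any(known)) stop("no mutations with known clonality; proportion undefined")
  out <- mean(clonality[known] == "subclonal")
  attr(out, "n_unknown") <- sum(!known)
  out
}

#' Count subclones across a tumor pair
#'
#' Counts subclones present in either tumor (pre- or post-treatment CCF
#' above zero); a subclone shared by both tumors counts once.
#'
#' @param subclones Data.frame with `pre_ccf` and `post_ccf` columns (one
#'   row per subclone of one patient).
#' @return Integer count.
#' @export
count_subclones <- function(subclones) {
  if (nrow(subclones) == 0) return(0L)
  sum(subclones$pre_ccf > 0 | subclones$post_ccf > 0)
}

#' Per-patient heterogeneity covariates
#'
#' Assembles the intratumoral-heterogeneity metrics used as survival
#' covariates: per-tumor subclonal proportions and the total subclone
#' count, with high/low flags at the conventional cutoffs (0.2 subclonal
#' proportion; 6 subclones). "High" means strictly greater than the cutoff;
#' both cutoffs are configurable. Clinical pass-through columns are copied
#' unchanged for external survival tooling -- survival modeling itself is
#' out of scope here.
#'
#' @param pre,post Mutation data.frames with `patient` and `clonality`.
#' @param subclones Data.frame with `patient`, `pre_ccf`, `post_ccf`.
#' @param clinical Optional per-patient data.frame (keyed by `patient`)
#'   whose columns are passed through.
#' @param prop_cutoff Subclonal-proportion cutoff (default 0.2).
#' @param subclone_cutoff Subclone-count cutoff (default 6).
#' @return Data.frame with one row per patient: `patient`,
#'   `prop_subclonal_pre`, `prop_subclonal_post`, `n_subclones`,
#'   `high_het_pre`, `high_het_post`, `high_subclones`, plus clinical
#'   columns.
#' @export
heterogeneity_metrics <- function(pre, post, subclones, clinical = NULL,
                                  prop_cutoff = 0.2, subclone_cutoff = 6) {
  patients <- sort(unique(c(as.character(pre$patient),
                            as.character(post$patient))))
  prop_of <- function(df, p) {
    cl <- df$clonality[df$patient == p]
    if (!any(cl %in% c("clonal", "subclonal"))) return(NA_real_)
    as.numeric(proportion_subclonal(cl))
  }
  out <- data.frame(patient = patients, stringsAsFactors = FALSE)
  out$prop_subclonal_pre <- vapply(patients, prop_of, numeric(1), df = pre)
  out$prop_subclonal_post <- vapply(patients, prop_of, numeric(1), df = post)
  out$n_subclones <- vapply(patients, function(p) {
    count_subclones(subclones[subclones$patient == p, , drop = FALSE])
  }, integer(1))
  out$high_het_pre <- out$prop_subclonal_pre > prop_cutoff
  out$high_het_post <- out$prop_subclonal_post > prop_cutoff
  out$high_subclones <- out$n_subclones > subclone_cutoff
  if (!is.null(clinical)) {
    out <- merge(out, clinical, by = "patient", all.x = TRUE, sort = TRUE)
  }
  out
}

#' Paired and group comparisons of mutation loads
#'
#' Compares paired pre/post mutation counts with a two-sided paired t-test
#' (null: mean difference 0) and, when shared-mutation counts are given,
#' compares the private-pre vs shared and shared vs private-post count
#' groups with two-sided Wilcoxon rank-sum tests.
#'
#' @param pre_counts,post_counts Equal-length per-patient mutation counts
#'   (n >= 2).
#' @param shared_counts Optional per-patient shared-mutation counts.
#' @return List: `mean_change` (post - pre), `t_p`, `degenerate` (TRUE when
#'   the paired differences have zero variance, in which case `t_p` is 1
#'   for a zero shift and 0 otherwise), and when `shared_counts` is given
#'   `wilcox_pre_shared_p`, `wilcox_shared_post_p`.
#' @export
compare_loads <- function(pre_counts, post_counts, shared_counts = NULL) {
  if (length(pre_counts) != length(post_counts)) {
    stop("pre and post count vectors differ in length")
  }
  if (length(pre_counts) < 2) stop("need at least two patients")
  d <- post_counts - pre_counts
  degenerate <- stats::sd(d) == 0
  t_p <- if (degenerate) {
    if (mean(d) == 0) 1 else 0
  } else {
    stats::t.test(d)$p.value
  }
  out <- list(mean_change = mean(d), t_p = t_p, degenerate = degenerate)
  if (!is.null(shared_counts)) {
    out$wilcox_pre_shared_p <-
      stats::wilcox.test(pre_counts, shared_counts, exact = FALSE)$p.value
    out$wilcox_shared_post_p <-
      stats::wilcox.test(shared_counts, post_counts, exact = FALSE)$p.value
  }
  out
}
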