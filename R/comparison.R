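#' Chi-squared comparison of cohort and reference category distributions
#'
#' Pearson's chi-squared test on the k x 2 contingency table of cohort versus
#' reference counts for one categorical characteristic, with
#' \eqn{df = k - 1}.  Counts are required; if both columns look like
#' percentages (each summing to about 100) the error message points to
#' \code{\link{reconstruct_counts}}.
#'
#' @param cohort_counts,reference_counts non-negative counts per category
#'   (equal length), or pass a data frame with columns \code{cohort_count}
#'   and \code{reference_count} as \code{cohort_counts}.
#' @param correct apply Yates' continuity correction?  Off by default, the
#'   convention for multi-category tables with large totals.
#' @return List with \code{statistic}, \code{df}, \code{p_value} and the
#'   \code{expected} cell counts.
#' @export
chi_square_compare <- function(cohort_counts, reference_counts = NULL,
                               correct = FALSE) {
  if (is.data.frame(cohort_counts)) {
    df <- cohort_counts
    stopifnot(all(c("cohort_count", "reference_count") %in% names(df)))
    reference_counts <- df$reference_count
    cohort_counts <- df$cohort_count
  }
  stopifnot(length(cohort_counts) == length(reference_counts),
            length(cohort_counts) >= 2)
  non_integer <- any(abs(c(cohort_counts, reference_counts) -
                           round(c(cohort_counts, reference_counts))) > 1e-9)
  if (non_integer && abs(sum(cohort_counts) - 100) < 0.5 &&
      abs(sum(reference_counts) - 100) < 0.5)
    stop("inputs look like percentages; reconstruct counts first with ",
         "reconstruct_counts(pct, total_n)")
  tab <- cbind(cohort = cohort_counts, reference = reference_counts)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0))
    stop("expected cell count of zero in category ", which(expected <= 0)[1])
  ht <- stats::chisq.test(tab, correct = correct)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Reconstruct category counts from published percentages
#'
#' Published comparison tables usually report percentages and a total
#' \eqn{N}; tests need counts.  Counts are \code{round(pct/100 * N)}.  When
#' the rounded counts miss \eqn{N} by at most \eqn{k/2} (a pure rounding
#' artifact) they are repaired by the largest-remainder rule; a larger
#' discrepancy reflects rounding in the published percentages themselves and
#' is preserved and reported rather than redistributed.
#'
#' @param percentages per-category percentages summing to 100 within
#'   \code{tolerance}.
#' @param total_n the published total.
#' @param tolerance allowed deviation of the percentage sum from 100.
#' @return Integer vector of counts.
#' @export
reconstruct_counts <- function(percentages, total_n, tolerance = 0.5) {
  s <- sum(percentages)
  if (abs(s - 100) > tolerance)
    stop(sprintf("percentages sum to %.2f, outside 100 +/- %.2f", s, tolerance))
  raw <- percentages / 100 * total_n
  counts <- round(raw)
  disc <- sum(counts) - total_n
  k <- length(percentages)
  if (disc != 0 && abs(disc) <= k / 2) {
    # largest-remainder repair: floor, then hand out the missing units to the
    # categories with the largest fractional parts
    counts <- floor(raw)
    need <- total_n - sum(counts)
    if (need > 0) {
      top <- order(raw - counts, decreasing = TRUE)[seq_len(need)]
      counts[top] <- counts[top] + 1
    }
  } else if (disc != 0) {
    message(sprintf("reconstructed counts sum to %d, published N = %d (difference %+d left as-is)",
                    sum(counts), total_n, disc))
  }
  as.integer(counts)
}

#' Counterfactual reweighting of cumulative mortality
#'
#' Direct standardisation: the cohort's cumulative mortality at a horizon is
#' recomputed as if one baseline characteristic had a different (e.g. a
#' reference survey's) category distribution.  Per-category cumulative
#' mortality \eqn{M_k = 1 - CP_k(horizon)} comes from the actuarial
#' life-table stage run within category \eqn{k}; the observed and
#' counterfactual mortalities are \eqn{\sum_k \hat\pi_k M_k} and
#' \eqn{\sum_k \pi^{target}_k M_k}, where \eqn{\hat\pi_k} are the cohort's
#' (weighted) category proportions.  A ratio above 1 means the cohort's
#' mortality would rise under the target composition — the size of the
#' healthy-volunteer contribution of that characteristic.
#'
#' @inheritParams tabulate_intervals
#' @param covariate name of a categorical column of \code{records}.
#' @param target_dist named proportions over the covariate's categories,
#'   summing to 1.
#' @param horizon evaluation time in years; must be a multiple of
#'   \code{width} and within every category's follow-up.
#' @return List with \code{mortality_observed}, \code{mortality_reweighted},
#'   \code{ratio} and a per-category breakdown data frame.
#' @export
counterfactual_reweight <- function(records, covariate, target_dist, horizon,
                                    width = 1, weighted = TRUE) {
  records <- validate_cohort(records)
  if (!covariate %in% names(records)) stop("no such covariate: ", covariate)
  if (abs(sum(target_dist) - 1) > 1e-6)
    stop("target proportions must sum to 1")
  n_int <- horizon / width
  if (abs(n_int - round(n_int)) > 1e-9)
    stop("horizon must be a whole number of intervals")
  n_int <- as.integer(round(n_int))

  cats <- names(target_dist)
  obs_cats <- unique(as.character(records[[covariate]]))
  if (length(setdiff(cats, obs_cats)))
    stop("target category absent from cohort: ",
         paste(setdiff(cats, obs_cats), collapse = ", "))
  if (length(setdiff(obs_cats, cats)))
    stop("cohort category missing from target distribution: ",
         paste(setdiff(obs_cats, cats), collapse = ", "))

  w <- if (weighted) records$weight else rep(1, nrow(records))
  pi_obs <- vapply(cats, function(k) sum(w[records[[covariate]] == k]), numeric(1))
  pi_obs <- pi_obs / sum(pi_obs)

  M <- vapply(cats, function(k) {
    sub <- records[records[[covariate]] == k, , drop = FALSE]
    counts <- tabulate_intervals(sub, width = width, weighted = weighted)
    if (nrow(counts) < n_int)
      stop("horizon exceeds follow-up in category ", k)
    counts <- counts[seq_len(n_int), , drop = FALSE]
    if (any(counts$L - counts$W / 2 <= 0))
      stop("category with zero at-risk before the horizon: ", k)
    obs <- observed_survival(counts)
    1 - obs$CP[n_int]
  }, numeric(1))

  m_obs <- sum(pi_obs * M)
  m_cf <- sum(target_dist[cats] * M)
  list(mortality_observed = m_obs,
       mortality_reweighted = m_cf,
       ratio = m_cf / m_obs,
       by_category = data.frame(category = cats,
                                cumulative_mortality = unname(M),
                                prop_observed = unname(pi_obs),
                                prop_target = unname(target_dist[cats])))
}
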