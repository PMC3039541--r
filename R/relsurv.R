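#' Tabulate a cohort into annual life-table intervals
#'
#' Bins each record's endpoint into half-open intervals
#' \eqn{[i \cdot width, (i+1) \cdot width)}: a death at time \eqn{t} adds to
#' the deaths \eqn{D} of interval \eqn{\lfloor t / width \rfloor}, a censoring
#' adds to the withdrawals \eqn{W} of that interval, and an endpoint exactly
#' on a boundary belongs to the interval starting there.  The at-risk count
#' \eqn{L} of interval 0 is the (weighted) cohort size and satisfies
#' \eqn{L_{i+1} = L_i - D_i - W_i}.  With \code{weighted = TRUE} every
#' contribution is the record's sampling weight, otherwise 1.
#'
#' @param records a cohort data frame (see \code{\link{read_cohort}}).
#' @param width interval length in years (> 0).
#' @param weighted use sampling weights?
#' @param max_intervals optional cap on the number of intervals returned;
#'   records still in follow-up beyond the cap contribute only to \eqn{L}.
#' @return Data frame with columns \code{interval} (0-based), \code{start},
#'   \code{end}, \code{L}, \code{D}, \code{W}.
#' @export
tabulate_intervals <- function(records, width = 1, weighted = TRUE,
                               max_intervals = NULL) {
  stopifnot(width > 0)
  if (nrow(records) == 0L) stop("cannot tabulate an empty cohort")
  w <- if (weighted) records$weight else rep(1, nrow(records))
  k <- floor(records$follow_up / width)          # terminal interval index
  n_int <- max(k) + 1L
  if (!is.null(max_intervals)) n_int <- min(n_int, as.integer(max_intervals))

  idx <- k + 1L
  D <- W <- numeric(n_int)
  inb <- idx <= n_int
  dsum <- rowsum(w[inb] * (records$event[inb] == 1), idx[inb])
  wsum <- rowsum(w[inb] * (records$event[inb] == 0), idx[inb])
  D[as.integer(rownames(dsum))] <- dsum[, 1]
  W[as.integer(rownames(wsum))] <- wsum[, 1]
  # L_i = total weight of records whose terminal interval is >= i
  exit_w <- numeric(n_int)
  es <- rowsum(w[inb], idx[inb])
  exit_w[as.integer(rownames(es))] <- es[, 1]
  total <- sum(w)
  L <- total - c(0, cumsum(exit_w))[seq_len(n_int)]

  data.frame(interval = seq_len(n_int) - 1L,
             start = (seq_len(n_int) - 1L) * width,
             end = seq_len(n_int) * width,
             L = L, D = D, W = W)
}

#' Actuarial observed survival from interval counts
#'
#' Applies the classical actuarial convention that deaths and withdrawals are
#' evenly distributed over the interval: effective at-risk
#' \eqn{L' = L - W/2}, interval survival \eqn{P = 1 - D/L'}, and cumulative
#' survival by the product recursion \eqn{CP_{i+1} = CP_i P_i} with
#' \eqn{CP_0 = 1} (the value reported for interval \eqn{i} is the cumulative
#' survival at its end).
#'
#' @param counts data frame with columns \code{L}, \code{D}, \code{W} (and
#'   optionally \code{interval}, \code{start}, \code{end}, carried through).
#' @return The input with columns \code{L_eff}, \code{P}, \code{CP} appended;
#'   intervals with \eqn{L' \le 0} are dropped with a warning.
#' @export
observed_survival <- function(counts) {
  stopifnot(all(c("L", "D", "W") %in% names(counts)))
  L_eff <- counts$L - counts$W / 2
  drop <- L_eff <= 0
  if (any(drop)) {
    warning(sum(drop), " interval(s) dropped: effective at-risk <= 0")
    counts <- counts[!drop, , drop = FALSE]
    L_eff <- L_eff[!drop]
  }
  if (any(counts$D > L_eff))
    stop("deaths exceed effective at-risk in interval ",
         counts$interval[which(counts$D > L_eff)[1]])
  counts$L_eff <- L_eff
  counts$P <- 1 - counts$D / L_eff
  counts$CP <- cumprod(counts$P)
  counts
}

#' Ederer II expected survival
#'
#' For each interval the expected deaths \eqn{D^*} are accumulated over the
#' cohort members still at risk at the interval start: member \eqn{j}
#' contributes \eqn{w_j q^*_{ij}}, their population death probability at
#' attained age \code{entry_age + i} and attained calendar year
#' \code{entry_year + i} in their stratum; members censored within the
#' interval contribute \eqn{w_j q^*_{ij} / 2}, mirroring the \eqn{L - W/2}
#' exposure convention.  Expected interval survival is
#' \eqn{P^* = 1 - D^*/L'} and \eqn{CP^*} follows the same product recursion
#' as the observed series.
#'
#' @inheritParams tabulate_intervals
#' @param table a \code{\link{as_poplifetable}} object.
#' @param year_mode \code{"attained"} matches life-table calendar year to
#'   each member's attained year (entry_year + interval); \code{"fixed"}
#'   always uses the entry year.
#' @return Data frame with columns \code{interval}, \code{D_star},
#'   \code{P_star}, \code{CP_star}.
#' @export
ederer2_expected <- function(records, table, width = 1, weighted = TRUE,
                             max_intervals = NULL,
                             year_mode = c("attained", "fixed")) {
  year_mode <- match.arg(year_mode)
  counts <- tabulate_intervals(records, width = width, weighted = weighted,
                               max_intervals = max_intervals)
  n_int <- nrow(counts)
  w <- if (weighted) records$weight else rep(1, nrow(records))
  k <- floor(records$follow_up / width)

  # person x interval grid over the at-risk period of each record
  n_at_risk <- pmin(k + 1L, n_int)
  rec <- rep.int(seq_len(nrow(records)), n_at_risk)
  iv <- sequence(n_at_risk) - 1L               # 0-based interval index
  age <- records$entry_age[rec] + floor(iv * width)
  yr <- if (year_mode == "attained") records$entry_year[rec] + floor(iv * width)
        else records$entry_year[rec]
  q <- lookup_q(table, records$stratum[rec], yr, age)
  if (width != 1) q <- 1 - (1 - q)^width
  contrib <- w[rec] * q
  half <- iv == k[rec] & records$event[rec] == 0   # censored within interval
  contrib[half] <- contrib[half] / 2

  D_star <- numeric(n_int)
  ds <- rowsum(contrib, iv + 1L)
  D_star[as.integer(rownames(ds))] <- ds[, 1]
  L_eff <- counts$L - counts$W / 2
  P_star <- 1 - D_star / L_eff
  data.frame(interval = counts$interval, D_star = D_star,
             P_star = P_star, CP_star = cumprod(P_star))
}

#' Interval-specific and cumulative relative survival ratios
#'
#' \eqn{R = P / P^*} and \eqn{CR = CP / CP^*}; ratios are not clamped and may
#' fall on either side of 1 (values above 1 indicate survival better than the
#' matched population).
#'
#' @param observed data frame with columns \code{P}, \code{CP}.
#' @param expected data frame with columns \code{P_star}, \code{CP_star}.
#' @return Data frame with columns \code{R}, \code{CR}.
#' @export
relative_ratios <- function(observed, expected) {
  stopifnot(nrow(observed) == nrow(expected))
  bad <- which(expected$P_star <= 0 | expected$CP_star <= 0)
  if (length(bad))
    stop("expected survival is zero or negative in interval ", bad[1] - 1L)
  data.frame(R = observed$P / expected$P_star,
             CR = observed$CP / expected$CP_star)
}

#' Greenwood-type confidence interval for cumulative relative survival
#'
#' Uses the Greenwood estimator of the variance of \eqn{\log CP},
#' \deqn{\widehat{var}(\log CP_i) = \sum_{k \le i} D_k / \{L'_k (L'_k - D_k)\},}
#' treats the expected survival \eqn{CP^*} as fixed (it derives from national
#' life tables whose sampling error is negligible relative to the cohort's),
#' and forms \eqn{\exp\{\log CR \pm z \sqrt{\widehat{var}}\}}.
#'
#' @param rows data frame with columns \code{L_eff}, \code{D}, \code{CR}.
#' @param level coverage probability (default 0.95).
#' @return Data frame with columns \code{ci_low}, \code{ci_high}.
#' @export
cr_confidence_interval <- function(rows, level = 0.95) {
  stopifnot(all(c("L_eff", "D", "CR") %in% names(rows)), level > 0, level < 1)
  if (any(rows$L_eff == rows$D))
    stop("variance undefined: all effective at-risk die in interval ",
         rows$interval[which(rows$L_eff == rows$D)[1]])
  v <- cumsum(rows$D / (rows$L_eff * (rows$L_eff - rows$D)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(ci_low = exp(log(rows$CR) - z * sqrt(v)),
             ci_high = exp(log(rows$CR) + z * sqrt(v)))
}

#' Relative-survival life table
#'
#' The full estimation pipeline producing one row per follow-up interval:
#' tabulation of at-risk, deaths and withdrawals; actuarial observed survival;
#' Ederer II expected survival from a population life table (or an injected
#' expected-survival series for validation against published tables); relative
#' survival ratios; and Greenwood-type confidence intervals for the cumulative
#' ratio.
#'
#' Either supply \code{records} and \code{table}, or supply pre-tabulated
#' \code{counts} (columns \code{L, D, W}) together with \code{expected}: a
#' numeric vector of per-interval expected survival probabilities
#' \eqn{P^*}, or a data frame with column \code{P_star} and optionally
#' \code{CP_star} (used as given, e.g. when reproducing a published table
#' whose cumulative column carries more information than its rounded
#' per-interval column).
#'
#' @inheritParams ederer2_expected
#' @param counts optional pre-tabulated interval counts.
#' @param expected optional injected expected survival (see Details).
#' @param conf_level coverage of the confidence interval.
#' @return An object of class \code{rs_lifetable}: a data frame with columns
#'   \code{interval, start, end, L, D, W, L_eff, P, CP, D_star, P_star,
#'   CP_star, R, CR, ci_low, ci_high}.
#' @examples
#' lt <- as_poplifetable(data.frame(stratum = "S", year = 1996, age = 70:85,
#'                                  qx = 0.02 * 1.09^(0:15)))
#' cohort <- data.frame(id = 1:500, entry_age = 70, entry_year = 1996,
#'                      follow_up = pmin(rexp(500, 0.03), 10), weight = 1,
#'                      stratum = "S")
#' cohort$event <- as.numeric(cohort$follow_up < 10)
#' fit <- rs_lifetable(cohort, lt)
#' summary(fit)
#' @export
rs_lifetable <- function(records = NULL, table = NULL, counts = NULL,
                         expected = NULL, width = 1, weighted = TRUE,
                         conf_level = 0.95, max_intervals = NULL,
                         year_mode = c("attained", "fixed")) {
  year_mode <- match.arg(year_mode)
  cl <- match.call()
  if (is.null(counts)) {
    if (is.null(records))
      stop("supply either records, or pre-tabulated counts")
    if (is.null(table) && is.null(expected))
      stop("expected survival requires a population life table or an injected series")
    records <- validate_cohort(records)
    counts <- tabulate_intervals(records, width = width, weighted = weighted,
                                 max_intervals = max_intervals)
  } else {
    stopifnot(all(c("L", "D", "W") %in% names(counts)))
    if (is.null(counts$interval)) counts$interval <- seq_len(nrow(counts)) - 1L
    if (is.null(counts$start)) counts$start <- counts$interval * width
    if (is.null(counts$end)) counts$end <- counts$start + width
  }
  obs <- observed_survival(counts)

  if (!is.null(expected)) {
    if (is.numeric(expected))
      expected <- data.frame(P_star = expected)
    if (is.null(expected$P_star))
      stop("injected expected survival needs a P_star column or numeric vector")
    if (nrow(expected) != nrow(obs))
      stop(sprintf("expected survival has %d intervals, counts have %d",
                   nrow(expected), nrow(obs)))
    if (is.null(expected$CP_star)) expected$CP_star <- cumprod(expected$P_star)
    if (is.null(expected$D_star)) expected$D_star <- obs$L_eff * (1 - expected$P_star)
    exp_df <- expected[, c("D_star", "P_star", "CP_star")]
  } else {
    if (is.null(records) || is.null(table))
      stop("expected survival requires a population life table or an injected series")
    exp_df <- ederer2_expected(records, table, width = width,
                               weighted = weighted,
                               max_intervals = max_intervals,
                               year_mode = year_mode)
    exp_df <- exp_df[match(obs$interval, exp_df$interval),
                     c("D_star", "P_star", "CP_star")]
  }

  out <- cbind(obs, exp_df, relative_ratios(obs, exp_df))
  out <- cbind(out, cr_confidence_interval(out, level = conf_level))
  rownames(out) <- NULL
  structure(out, class = c("rs_lifetable", "data.frame"),
            width = width, weighted = weighted, conf_level = conf_level,
            call = cl)
}

#' @export
print.rs_lifetable <- function(x, digits = 3, ...) {
  cat("Relative-survival life table",
      if (isTRUE(attr(x, "weighted"))) "(weighted)" else "(unweighted)", "\n")
  disp <- data.frame(interval = sprintf("%.1f-%.1f", x$start, x$end),
                     L = trunc(x$L), D = round(x$D, 1), W = round(x$W, 1),
                     L_eff = trunc(x$L_eff),   # published tables truncate
                     P = round(x$P, digits), CP = round(x$CP, digits),
                     P_star = round(x$P_star, digits),
                     CP_star = round(x$CP_star, digits),
                     R = round(x$R, digits), CR = round(x$CR, digits),
                     ci_low = round(x$ci_low, digits),
                     ci_high = round(x$ci_high, digits))
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rs_lifetable <- function(object, ...) {
  n <- nrow(object)
  out <- list(n_intervals = n,
              horizon = object$end[n],
              total_deaths = sum(object$D),
              cumulative_observed = object$CP[n],
              cumulative_expected = object$CP_star[n],
              CR = object$CR[n],
              ci = c(object$ci_low[n], object$ci_high[n]),
              advantage_pct = 100 * (object$CR[n] - 1),
              conf_level = attr(object, "conf_level"))
  class(out) <- "summary.rs_lifetable"
  out
}

#' @export
print.summary.rs_lifetable <- function(x, ...) {
  cat(sprintf("Cumulative relative survival at %g years: %.3f (%d%% CI %.3f-%.3f)\n",
              x$horizon, x$CR, round(100 * x$conf_level), x$ci[1], x$ci[2]))
  cat(sprintf("Observed %.3f vs expected %.3f cumulative survival; deaths: %.0f\n",
              x$cumulative_observed, x$cumulative_expected, x$total_deaths))
  cat(sprintf("Relative survival advantage: %+.1f%%\n", x$advantage_pct))
  invisible(x)
}

#' @export
plot.rs_lifetable <- function(x, ...) {
  graphics::plot(x$end, x$CR, type = "b", pch = 16,
                 ylim = range(c(x$ci_low, x$ci_high, 1)),
                 xlab = "Years since entry",
                 ylab = "Cumulative relative survival", ...)
  graphics::arrows(x$end, x$ci_low, x$end, x$ci_high,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Subgroup relative survival (one life table per level)
#'
#' Re-runs the life-table stage within each level of a grouping column and
#' reports the cumulative relative survival at the last common interval, the
#' shape of a published subgroup table (one row per State/Territory,
#' remoteness category or entry age).
#'
#' @inheritParams rs_lifetable
#' @param by name of a column of \code{records} to stratify the analysis by.
#' @return Data frame with columns \code{level, n, deaths, CR, ci_low,
#'   ci_high}.
#' @export
rs_lifetable_by <- function(records, table, by, width = 1, weighted = TRUE,
                            conf_level = 0.95, max_intervals = NULL,
                            year_mode = c("attained", "fixed")) {
  if (!by %in% names(records)) stop("no such column: ", by)
  levels <- sort(unique(as.character(records[[by]])))
  rows <- lapply(levels, function(lv) {
    sub <- records[records[[by]] == lv, , drop = FALSE]
    fit <- rs_lifetable(sub, table, width = width, weighted = weighted,
                        conf_level = conf_level, max_intervals = max_intervals,
                        year_mode = year_mode)
    n <- nrow(fit)
    data.frame(level = lv, n = nrow(sub), deaths = sum(fit$D),
               CR = fit$CR[n], ci_low = fit$ci_low[n], ci_high = fit$ci_high[n])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
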