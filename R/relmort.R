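#' Split cohort follow-up into annual person-time cells
#'
#' Expands each record into \code{ceiling(follow_up / width)} cells aligned to
#' time since entry.  Cell \eqn{i} carries exposure \code{width} (the final
#' cell carries the remainder), the member's attained age
#' \code{entry_age + i} and attained calendar year \code{entry_year + i}, the
#' expected population hazard \code{mu_star} looked up at that age/year/
#' stratum, and the record's baseline covariates.  The death indicator sits
#' on the final cell only.
#'
#' @inheritParams ederer2_expected
#' @return Data frame with columns \code{id, interval, attained_age,
#'   attained_year, stratum, exposure, event, mu_star, weight} plus the
#'   cohort's covariate columns.  Records with zero follow-up and no event
#'   are dropped with a warning; zero follow-up with an event is an error
#'   (its likelihood contribution is undefined).
#' @export
split_person_time <- function(records, table, width = 1,
                              year_mode = c("attained", "fixed")) {
  year_mode <- match.arg(year_mode)
  records <- validate_cohort(records)
  zero <- records$follow_up == 0
  if (any(zero & records$event == 1))
    stop("record with zero follow-up and an event: id ",
         records$id[which(zero & records$event == 1)[1]])
  if (any(zero)) {
    warning(sum(zero), " record(s) with zero follow-up dropped")
    records <- records[!zero, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no records with positive follow-up")

  ncell <- ceiling(records$follow_up / width)
  rec <- rep.int(seq_len(nrow(records)), ncell)
  iv <- sequence(ncell) - 1L
  last <- iv == ncell[rec] - 1L
  exposure <- rep(width, length(iv))
  exposure[last] <- records$follow_up[rec[last]] - (ncell[rec[last]] - 1L) * width

  age <- records$entry_age[rec] + floor(iv * width)
  yr <- if (year_mode == "attained") records$entry_year[rec] + floor(iv * width)
        else records$entry_year[rec]
  # hazard is per year; the cell's exposure carries the interval width
  mu <- -log1p(-lookup_q(table, records$stratum[rec], yr, age))

  cells <- data.frame(id = records$id[rec], interval = iv,
                      attained_age = age, attained_year = yr,
                      stratum = records$stratum[rec],
                      exposure = exposure,
                      event = ifelse(last, records$event[rec], 0),
                      mu_star = mu, weight = records$weight[rec],
                      stringsAsFactors = FALSE)
  covs <- cohort_covariates(records)
  for (v in covs) cells[[v]] <- records[[v]][rec]
  cells
}

# Newton-Raphson with step-halving for the relative-mortality likelihood on
# aggregated covariate patterns.  O = sum of weighted events, E = sum of
# weighted expected events (mu_star * exposure) per pattern; up to a constant
# the log likelihood is sum_g O_g eta_g - E_g exp(eta_g), eta = X beta.
fit_relmort_newton <- function(X, O, E, max_iter = 50, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(O * eta - E * exp(eta))
  }
  ll_old <- ll(beta)
  trace <- ll_old
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- E * exp(eta)
    grad <- drop(crossprod(X, O - mu))
    info <- crossprod(X * sqrt(mu))
    step <- tryCatch(solve(info, grad), error = function(e)
      stop("information matrix is singular; check the design for aliasing"))
    # step-halving: the Newton direction may overshoot far from the optimum
    fac <- 1
    repeat {
      ll_new <- ll(beta + fac * step)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      fac <- fac / 2
      if (fac < 2^-30) { ll_new <- ll_old; break }
    }
    beta <- beta + fac * step
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll_old) < tol * (abs(ll_old) + 1)) {
      ll_old <- ll_new
      converged <- TRUE
      break
    }
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta)
  mu <- E * exp(eta)
  info <- crossprod(X * sqrt(mu))
  list(beta = beta, information = info, loglik = ll_old,
       converged = converged, n_iter = iter, fitted = mu, trace = trace)
}

#' Multiplicative relative-mortality regression
#'
#' Fits the proportional-hazards model
#' \deqn{\lambda_i(a, s, z_i) = \lambda^*_i(a, s) \, e^{\beta' z_i}}
#' in which the known population hazard \eqn{\lambda^*} (from a population
#' life table, by attained age \eqn{a}, calendar year and stratum \eqn{s})
#' is scaled by a log-linear function of baseline covariates.  A hazard ratio
#' below 1 means mortality below the matched population, i.e. better relative
#' survival.  Because \eqn{\lambda^*} is fully specified, the likelihood on
#' annually split person-time is exact and coincides with a Poisson
#' likelihood with offset \eqn{\log(\mu^* \cdot exposure)}; it is maximised
#' by Newton-Raphson with analytic gradient and Hessian and step-halving.
#' With the default intercept, \eqn{e^{\beta_0}} is the overall standardised
#' mortality ratio of the reference category and the remaining hazard ratios
#' are relative to their reference levels, as in published tables.
#'
#' Sampling weights enter as pseudo-likelihood multipliers; the default
#' covariance is the inverse observed information (model-based).  With
#' \code{robust = TRUE} a cluster (by record) sandwich covariance is
#' reported instead.
#'
#' @param formula one-sided formula of baseline covariates, e.g.
#'   \code{~ smoking + self_rated_health}.  Use \code{~ x - 1} to omit the
#'   intercept (the reference-category hazard is then pinned to the
#'   population's).
#' @param data either a cohort data frame (split internally) or a data frame
#'   of person-time cells from \code{\link{split_person_time}}.
#' @param table a \code{\link{as_poplifetable}}; required when \code{data}
#'   are cohort records.
#' @param width splitting interval in years.
#' @param use_weights use sampling weights?
#' @param robust report a cluster sandwich covariance?
#' @param max_iter,tol Newton-Raphson controls (relative log-likelihood
#'   change below \code{tol} declares convergence).
#' @param year_mode see \code{\link{split_person_time}}.
#' @return An object of class \code{relmort} with components
#'   \code{coefficients}, \code{vcov}, \code{loglik}, \code{n_events},
#'   \code{n_cells}, \code{converged}, \code{n_iter} and the usual
#'   model-frame metadata; methods: \code{print}, \code{summary},
#'   \code{coef}, \code{vcov}, \code{confint}, \code{logLik},
#'   \code{predict}, \code{residuals}, and \code{\link{hazard_ratio_table}}.
#' @examples
#' lt <- as_poplifetable(data.frame(stratum = "S", year = 1996, age = 60:90,
#'                                  qx = 0.01 * 1.08^(0:30)))
#' set.seed(1)
#' coh <- data.frame(id = 1:300, entry_age = 70, entry_year = 1996,
#'                   follow_up = pmin(rexp(300, 0.05), 10), weight = 1,
#'                   stratum = "S",
#'                   smoker = sample(c("no", "yes"), 300, TRUE))
#' coh$event <- as.numeric(coh$follow_up < 10)
#' fit <- relmort(~ smoker, coh, lt)
#' summary(fit)
#' @export
relmort <- function(formula, data, table = NULL, width = 1,
                    use_weights = TRUE, robust = FALSE,
                    max_iter = 50, tol = 1e-8,
                    year_mode = c("attained", "fixed")) {
  year_mode <- match.arg(year_mode)
  cl <- match.call()
  if (length(formula) == 3L)
    stop("formula must be one-sided; the outcome is the cohort's event/follow_up")

  is_cells <- all(c("exposure", "mu_star") %in% names(data))
  cells <- if (is_cells) data else {
    if (is.null(table)) stop("a population life table is required to split person-time")
    split_person_time(data, table, width = width, year_mode = year_mode)
  }

  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(cells))
  if (length(missing_vars))
    stop("covariate(s) not found: ", paste(missing_vars, collapse = ", "))
  cc <- stats::complete.cases(cells[, vars, drop = FALSE])
  n_dropped <- length(unique(cells$id[!cc]))
  if (n_dropped > 0) {
    message(n_dropped, " record(s) excluded for missing covariates (complete-case analysis)")
    cells <- cells[cc, , drop = FALSE]
  }
  if (nrow(cells) == 0L) stop("no usable person-time cells")

  mf <- stats::model.frame(formula, cells)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    dropcol <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(dropcol, collapse = ", "))
  }

  w <- if (use_weights) cells$weight else rep(1, nrow(cells))
  d <- cells$event
  if (sum(d) < 1) stop("no events in the data")
  if (any(cells$exposure <= 0)) stop("non-positive exposure in person-time cells")

  o <- w * d                       # weighted observed events per cell
  e <- w * cells$mu_star * cells$exposure  # weighted expected events per cell
  if (any(d > 0 & cells$mu_star <= 0))
    stop("cell with an event but zero expected hazard: likelihood is unbounded")

  # aggregate by covariate pattern: the likelihood depends on the cells only
  # through the per-pattern sums of o and e
  pat <- do.call(paste, c(as.data.frame(X), sep = "\r"))
  gi <- match(pat, unique(pat))
  Xg <- X[!duplicated(pat), , drop = FALSE]
  O <- drop(rowsum(o, gi))
  E <- drop(rowsum(e, gi))

  fit <- fit_relmort_newton(Xg, O, E, max_iter = max_iter, tol = tol)
  if (!fit$converged)
    warning("Newton-Raphson did not converge in ", max_iter, " iterations")
  beta <- fit$beta
  names(beta) <- colnames(X)
  vc <- solve(fit$information)
  dimnames(vc) <- list(colnames(X), colnames(X))

  if (robust) {
    eta <- drop(X %*% beta)
    sc <- X * (o - e * exp(eta))          # per-cell score contributions
    sid <- rowsum(sc, cells$id)           # cluster by record
    meat <- crossprod(sid)
    vc <- solve(fit$information) %*% meat %*% solve(fit$information)
    dimnames(vc) <- list(colnames(X), colnames(X))
  }

  # full log likelihood includes the constant sum w * d * log(mu_star)
  loglik <- fit$loglik + sum((o * log(cells$mu_star))[d > 0])

  structure(list(coefficients = beta, vcov = vc, loglik = loglik,
                 hazard_ratios = exp(beta),
                 n_events = sum(d), n_cells = nrow(cells),
                 n_records = length(unique(cells$id)),
                 n_dropped = n_dropped,
                 total_observed = sum(o), total_expected = sum(e),
                 converged = fit$converged, n_iter = fit$n_iter,
                 loglik_trace = fit$trace,
                 pattern = list(X = Xg, O = O, E = E,
                                fitted = drop(Xg %*% beta)),
                 terms = stats::terms(mf),
                 xlevels = stats::.getXlevels(stats::terms(mf), mf),
                 contrasts = attr(X, "contrasts"),
                 assign = attr(X, "assign"),
                 robust = robust, use_weights = use_weights,
                 call = cl),
            class = "relmort")
}

#' @export
coef.relmort <- function(object, ...) object$coefficients

#' @export
vcov.relmort <- function(object, ...) object$vcov

#' @export
logLik.relmort <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_cells, class = "logLik")
}

#' @export
confint.relmort <- function(object, parm, level = 0.95, ...) {
  b <- object$coefficients
  if (missing(parm)) parm <- names(b)
  se <- sqrt(diag(object$vcov))[parm]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(b[parm] - z * se, b[parm] + z * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' @export
print.relmort <- function(x, digits = 4, ...) {
  cat("Multiplicative relative-mortality model\n")
  cat("  events:", x$n_events, " person-time cells:", x$n_cells,
      " records:", x$n_records, "\n")
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  cat("Hazard ratios (exp(beta)):\n")
  print(round(exp(x$coefficients), digits))
  invisible(x)
}

#' @export
summary.relmort <- function(object, level = 0.95, ...) {
  b <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- b / se
  tab <- cbind(beta = b, se = se, z = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)),
               HR = exp(b),
               ci_low = exp(b - stats::qnorm(1 - (1 - level) / 2) * se),
               ci_high = exp(b + stats::qnorm(1 - (1 - level) / 2) * se))
  out <- list(coefficients = tab, loglik = object$loglik,
              n_events = object$n_events, n_cells = object$n_cells,
              n_records = object$n_records, converged = object$converged,
              n_iter = object$n_iter, robust = object$robust,
              smr = object$total_observed / object$total_expected,
              call = object$call, level = level)
  class(out) <- "summary.relmort"
  out
}

#' @export
print.summary.relmort <- function(x, digits = 4, ...) {
  cat("Multiplicative relative-mortality model\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Records: %d   events: %d   person-time cells: %d\n",
              x$n_records, x$n_events, x$n_cells))
  cat(sprintf("Crude SMR (observed/expected deaths): %.3f\n", x$smr))
  cat(if (x$robust) "Cluster-robust (sandwich) standard errors\n"
      else "Model-based (inverse information) standard errors\n")
  stats::printCoefmat(x$coefficients[, c("beta", "se", "z", "Pr(>|z|)"), drop = FALSE],
               digits = digits)
  cat(sprintf("\nHazard ratios with %d%% Wald confidence limits:\n",
              round(100 * x$level)))
  print(round(x$coefficients[, c("HR", "ci_low", "ci_high"), drop = FALSE], 3))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  cat(sprintf("Log likelihood: %.3f (%d Newton iterations)\n", x$loglik, x$n_iter))
  invisible(x)
}

#' @export
predict.relmort <- function(object, newdata, type = c("hr", "link"), ...) {
  type <- match.arg(type)
  if (missing(newdata)) {
    eta <- object$pattern$fitted
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf, contrasts.arg = object$contrasts)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "hr") exp(eta) else eta
}

#' @export
residuals.relmort <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  with(object$pattern, {
    mu <- E * exp(fitted)
    r <- O - mu
    if (type == "pearson") r / sqrt(pmax(mu, .Machine$double.eps)) else r
  })
}

#' Hazard-ratio table in publication layout
#'
#' One row per covariate level with the hazard ratio and Wald confidence
#' limits; reference levels are printed with a hazard ratio of 1.00 and empty
#' limits, and rows follow the declared covariate and level order.
#'
#' @param fit a converged \code{\link{relmort}} fit.
#' @param level confidence level.
#' @return Data frame with columns \code{covariate, level, hazard_ratio,
#'   ci_low, ci_high, beta, se}.
#' @export
hazard_ratio_table <- function(fit, level = 0.95) {
  if (!fit$converged) stop("fit did not converge; no table produced")
  b <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  labels <- attr(fit$terms, "term.labels")
  rows <- list()
  if ("(Intercept)" %in% names(b)) {
    i <- "(Intercept)"
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = "(baseline)", level = "SMR",
      hazard_ratio = exp(b[i]), ci_low = exp(b[i] - z * se[i]),
      ci_high = exp(b[i] + z * se[i]), beta = b[i], se = se[i])
  }
  for (j in seq_along(labels)) {
    term <- labels[j]
    idx <- which(fit$assign == j)
    cn <- names(b)[idx]
    if (term %in% names(fit$xlevels)) {
      lvls <- fit$xlevels[[term]]
      ref <- setdiff(lvls, sub(paste0("^", term), "", cn))
      for (r in ref)
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = term, level = paste0(r, " (ref)"),
          hazard_ratio = 1, ci_low = NA_real_, ci_high = NA_real_,
          beta = 0, se = NA_real_)
      for (i in idx) {
        nm <- sub(paste0("^", term), "", names(b)[i])
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = term, level = nm,
          hazard_ratio = exp(b[i]), ci_low = exp(b[i] - z * se[i]),
          ci_high = exp(b[i] + z * se[i]), beta = b[i], se = se[i])
      }
    } else {
      for (i in idx)
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = term, level = names(b)[i],
          hazard_ratio = exp(b[i]), ci_low = exp(b[i] - z * se[i]),
          ci_high = exp(b[i] + z * se[i]), beta = b[i], se = se[i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
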