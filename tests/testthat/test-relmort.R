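test_that("person-time splitting produces annual cells with the event last", {
  lt <- flat_lifetable(0.02)
  cells <- split_person_time(make_cohort(2.5, 1), lt)
  expect_equal(nrow(cells), 3L)
  expect_equal(cells$exposure, c(1, 1, 0.5))
  expect_equal(cells$attained_age, c(70, 71, 72))
  expect_equal(cells$attained_year, c(1996, 1997, 1998))
  expect_equal(cells$event, c(0, 0, 1))
  expect_equal(cells$mu_star, rep(-log(0.98), 3))

  whole <- split_person_time(make_cohort(2.0, 0), lt)
  expect_equal(whole$exposure, c(1, 1))

  set.seed(2)
  coh <- make_cohort(follow_up = rexp(100, 0.2), event = rbinom(100, 1, 0.5),
                     smoking = sample(c("yes", "no"), 100, TRUE))
  cells <- split_person_time(coh, lt)
  expect_equal(sum(cells$exposure), sum(coh$follow_up), tolerance = 1e-9)
  expect_equal(sum(cells$event), sum(coh$event))
  expect_true("smoking" %in% names(cells))

  expect_error(split_person_time(make_cohort(0, 1), lt), "zero follow-up")
  expect_warning(split_person_time(make_cohort(c(0, 1), c(0, 1)), lt), "dropped")
})

test_that("one binary covariate recovers the ratio of group SMRs exactly", {
  # grouped person-time: group 0 has 50 observed vs 50 expected deaths,
  # group 1 has 30 observed vs 20 expected; the MLE hazard ratio is the
  # SMR ratio (30/20)/(50/50) = 1.5
  cells <- data.frame(
    id = sprintf("g%03d", 1:160),
    exposure = 1,
    mu_star = c(rep(0.5, 100), rep(1 / 3, 60)),
    event = c(rep(1, 50), rep(0, 50), rep(1, 30), rep(0, 30)),
    weight = 1,
    x = rep(c("a", "b"), c(100, 60)))
  fit <- relmort(~ x, cells)
  hr <- exp(coef(fit)[["xb"]])
  expect_equal(hr, (30 / 20) / (50 / 50), tolerance = 1e-8)
  expect_equal(exp(coef(fit)[["(Intercept)"]]), 1, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("estimates match an independent Poisson fit with log-offset", {
  set.seed(42)
  n <- 450
  cells <- data.frame(
    id = sprintf("c%03d", seq_len(n)),
    exposure = runif(n, 0.2, 1),
    mu_star = runif(n, 0.02, 0.2),
    weight = 1,
    x1 = sample(c("low", "high"), n, TRUE),
    x2 = sample(c("u", "v", "w"), n, TRUE))
  eta <- 0.4 * (cells$x1 == "high") - 0.3 * (cells$x2 == "w") + 0.1
  cells$event <- rbinom(n, 1, pmin(1, cells$mu_star * cells$exposure * exp(eta) * 3))
  fit <- relmort(~ x1 + x2, cells)
  ref <- stats::glm(event ~ x1 + x2 + offset(log(mu_star * exposure)),
                    family = stats::poisson(), data = cells)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-6)
  expect_equal(sqrt(diag(vcov(fit))), sqrt(diag(vcov(ref))), tolerance = 1e-4)
})

test_that("collapsing cells with identical covariates and hazards leaves the fit unchanged", {
  set.seed(8)
  n <- 400
  cells <- data.frame(
    id = sprintf("c%03d", seq_len(n)),
    exposure = 1,
    mu_star = rep(c(0.05, 0.1), each = n / 2),
    weight = 1,
    x = rep(rep(c("a", "b"), each = n / 4), 2))
  cells$event <- rbinom(n, 1, cells$mu_star * 1.4^(cells$x == "b"))
  fit <- relmort(~ x, cells)

  agg <- aggregate(cbind(event = event, exposure = exposure) ~ x + mu_star,
                   data = cells, FUN = sum)
  agg$id <- sprintf("a%02d", seq_len(nrow(agg)))
  agg$weight <- 1
  fit2 <- relmort(~ x, agg)
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-8)
})

test_that("the likelihood is monotone over Newton iterations with step-halving", {
  set.seed(13)
  lt <- flat_lifetable(0.05)
  coh <- make_cohort(follow_up = pmin(rexp(800, 0.1), 12),
                     event = NA,
                     frail = sample(c("no", "yes"), 800, TRUE, prob = c(0.8, 0.2)))
  coh$event <- as.numeric(coh$follow_up < 12)
  fit <- relmort(~ frail, coh, lt)
  expect_true(all(diff(fit$loglik_trace) >= -1e-10))
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 50)
})

test_that("constant weights cancel: beta equals the unweighted fit", {
  set.seed(21)
  lt <- flat_lifetable(0.04)
  coh <- make_cohort(follow_up = pmin(rexp(500, 0.08), 10), event = NA,
                     weight = 3.7,
                     g = sample(c("p", "q"), 500, TRUE))
  coh$event <- as.numeric(coh$follow_up < 10)
  fw <- relmort(~ g, coh, lt, use_weights = TRUE)
  fu <- relmort(~ g, coh, lt, use_weights = FALSE)
  expect_equal(coef(fw), coef(fu), tolerance = 1e-10)
})

test_that("a covariate unrelated to survival estimates a null effect", {
  preset <- alswh_like_preset(n = 5000, seed = 77)
  cfg <- preset$config
  cfg$covariate_specs <- list(noise = c(a = 0.5, b = 0.5))
  cfg$beta_truth <- list()
  cfg$healthy_volunteer_factor <- 1
  coh <- simulate_cohort(cfg, preset$table)
  fit <- relmort(~ noise, coh, preset$table)
  b <- coef(fit)[["noiseb"]]
  se <- sqrt(diag(vcov(fit)))[["noiseb"]]
  expect_lt(abs(b), 3 * se)
  expect_lt(abs(coef(fit)[["(Intercept)"]]), 3 * sqrt(diag(vcov(fit)))[["(Intercept)"]])
})

test_that("degenerate designs and data are refused with clear errors", {
  lt <- flat_lifetable(0.02)
  coh <- make_cohort(follow_up = c(2, 3, 4), event = c(1, 1, 0),
                     dup1 = c("a", "b", "a"), dup2 = c("a", "b", "a"))
  expect_error(relmort(~ dup1 + dup2, coh, lt), "rank deficient|aliased")
  nocov <- make_cohort(follow_up = c(2, 3), event = c(0, 0))
  expect_error(relmort(~ 1, nocov, lt), "no events")
  cells <- data.frame(id = "a", exposure = 1, mu_star = 0, event = 1, weight = 1)
  expect_error(relmort(~ 1, cells), "zero expected hazard")
  expect_error(relmort(event ~ x, coh, lt), "one-sided")
})

test_that("hazard-ratio tables follow the published layout", {
  # build a converged fit, then pin its coefficients to a known value
  lt <- flat_lifetable(0.05)
  set.seed(3)
  coh <- make_cohort(follow_up = pmin(rexp(300, 0.1), 8), event = NA,
                     smoking = sample(c("never", "current"), 300, TRUE))
  coh$event <- as.numeric(coh$follow_up < 8)
  coh$smoking <- factor(coh$smoking, levels = c("never", "current"))
  fit <- relmort(~ smoking, coh, lt)
  fit$coefficients[] <- c(0.1, 0.6098)
  fit$vcov <- diag(c(0.01, 0.05^2))
  dimnames(fit$vcov) <- list(names(fit$coefficients), names(fit$coefficients))

  tab <- hazard_ratio_table(fit)
  expect_equal(tab$covariate, c("(baseline)", "smoking", "smoking"))
  expect_equal(tab$level, c("SMR", "never (ref)", "current"))
  ref <- tab[tab$level == "never (ref)", ]
  expect_equal(ref$hazard_ratio, 1)
  expect_true(is.na(ref$ci_low) && is.na(ref$ci_high))
  cur <- tab[tab$level == "current", ]
  expect_equal(round(cur$hazard_ratio, 2), 1.84)
  expect_equal(round(cur$ci_low, 2), 1.67)
  expect_equal(round(cur$ci_high, 2), 2.03)
})

test_that("model methods are coherent", {
  lt <- flat_lifetable(0.05)
  set.seed(9)
  coh <- make_cohort(follow_up = pmin(rexp(400, 0.1), 10), event = NA,
                     g = sample(c("a", "b"), 400, TRUE))
  coh$event <- as.numeric(coh$follow_up < 10)
  fit <- relmort(~ g, coh, lt)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  expect_equal(predict(fit, data.frame(g = c("a", "b")), type = "link"),
               c(coef(fit)[1], sum(coef(fit))), ignore_attr = TRUE)
  expect_s3_class(summary(fit), "summary.relmort")
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_length(residuals(fit), nrow(fit$pattern$X))
  rob <- relmort(~ g, coh, lt, robust = TRUE)
  expect_equal(coef(rob), coef(fit))
  expect_false(identical(vcov(rob), vcov(fit)))
})
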