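# hand-enumerated oracle: 5 subjects with deaths at 0.5 and 1.5, a censoring
# at 2.5, and two administratively censored after 3 years
five_subject_cohort <- function(weight = 1)
  make_cohort(follow_up = c(0.5, 1.5, 2.5, 3.5, 4.2),
              event = c(1, 1, 0, 0, 0), weight = weight)

test_that("interval tabulation matches hand enumeration and is linear in weights", {
  counts <- tabulate_intervals(five_subject_cohort(), weighted = FALSE)
  expect_equal(counts$L, c(5, 4, 3, 2, 1))
  expect_equal(counts$D, c(1, 1, 0, 0, 0))
  expect_equal(counts$W, c(0, 0, 1, 1, 1))
  doubled <- tabulate_intervals(five_subject_cohort(weight = 2), weighted = TRUE)
  expect_equal(doubled$L, 2 * counts$L)
  expect_equal(doubled$D, 2 * counts$D)
  expect_equal(doubled$W, 2 * counts$W)
  one <- tabulate_intervals(make_cohort(0.2, 1))
  expect_equal(one[, c("L", "D", "W")], data.frame(L = 1, D = 1, W = 0))
  expect_error(tabulate_intervals(make_cohort(1, 0)[0, ]), "empty")
})

test_that("tabulation agrees with an independent brute-force loop", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:50, 1)
    coh <- make_cohort(follow_up = round(rexp(n, 0.3), 2),
                       event = rbinom(n, 1, 0.6),
                       weight = sample(c(1, 0.5, 2), n, replace = TRUE))
    expect_equal(tabulate_intervals(coh)[, c("L", "D", "W")],
                 brute_force_tabulate(coh)[, c("L", "D", "W")])
  }
})

test_that("deaths, withdrawals and survivors conserve the weighted cohort size", {
  set.seed(7)
  coh <- make_cohort(follow_up = rexp(200, 0.2), event = rbinom(200, 1, 0.5),
                     weight = runif(200, 0.5, 4))
  counts <- tabulate_intervals(coh)
  expect_equal(sum(counts$D) + sum(counts$W), sum(coh$weight), tolerance = 1e-9)
  expect_equal(counts$L[1], sum(coh$weight), tolerance = 1e-9)
  # the at-risk recursion L(i+1) = L(i) - D(i) - W(i)
  expect_equal(counts$L[-1],
               (counts$L - counts$D - counts$W)[-nrow(counts)],
               tolerance = 1e-9)
})

test_that("actuarial observed survival reproduces published interval rows", {
  # first and last rows of a published 12-interval cohort life table
  obs <- observed_survival(data.frame(L = c(12424, 9460), D = c(135, 398),
                                      W = c(0, 707), interval = 0:1))
  expect_equal(obs$L_eff, c(12424, 9106.5))
  expect_equal(round(obs$P, 3), c(0.989, 0.956))
  expect_equal(obs$P[1], 1 - 135 / 12424, tolerance = 1e-12)
  quiet <- observed_survival(data.frame(L = 10, D = 0, W = 0, interval = 0))
  expect_equal(quiet$P, 1)
  expect_equal(quiet$CP, 1)
  expect_error(observed_survival(data.frame(L = 10, D = 10, W = 2, interval = 0)),
               "exceed")
  expect_warning(observed_survival(data.frame(L = c(10, 1), D = c(0, 0),
                                              W = c(9, 2), interval = 0:1)),
                 "dropped")
})

test_that("Ederer II expected deaths follow the at-risk and half-exposure rules", {
  lt <- flat_lifetable(0.02)
  # homogeneous cohort, no withdrawals: expected survival is 1 - q throughout
  coh <- make_cohort(follow_up = rep(3.5, 4), event = 0)
  e <- ederer2_expected(coh, lt)
  expect_equal(e$P_star, rep(0.98, 4), tolerance = 1e-12)

  # two members with different q: expected deaths add
  lt2 <- as_poplifetable(expand.grid(stratum = c("A", "B"), year = 1996,
                                     age = 70, stringsAsFactors = FALSE) |>
                           transform(qx = c(0.01, 0.03)))
  coh2 <- make_cohort(follow_up = c(1, 1), event = c(1, 1), stratum = c("A", "B"))
  e2 <- ederer2_expected(coh2, lt2, max_intervals = 1)
  expect_equal(e2$D_star, 0.04, tolerance = 1e-12)
  expect_equal(e2$P_star, 0.98, tolerance = 1e-12)

  # a member censored mid-interval contributes half its death probability,
  # mirroring the L - W/2 exposure convention
  coh3 <- make_cohort(follow_up = c(1.5, 0.5), event = 0)
  e3 <- ederer2_expected(coh3, lt, max_intervals = 1)
  expect_equal(e3$D_star, 0.02 + 0.01, tolerance = 1e-12)
  expect_equal(e3$P_star, 1 - 0.03 / 1.5, tolerance = 1e-12)

  expect_error(ederer2_expected(make_cohort(1, 1, stratum = "X"), lt), "stratum")
})

test_that("relative ratios are plain ratios, unclamped", {
  rr <- relative_ratios(data.frame(P = 1 - 135 / 12424, CP = 0.72828),
                        data.frame(P_star = 0.981, CP_star = 0.665))
  expect_equal(round(rr$R, 3), 1.008)
  expect_equal(round(rr$CR, 3), 1.095)
  same <- relative_ratios(data.frame(P = c(0.9, 0.8), CP = c(0.9, 0.72)),
                          data.frame(P_star = c(0.9, 0.8), CP_star = c(0.9, 0.72)))
  expect_equal(same$R, c(1, 1))
  expect_equal(same$CR, c(1, 1))
  expect_error(relative_ratios(data.frame(P = 1, CP = 1),
                               data.frame(P_star = 0, CP_star = 1)), "interval 0")
})

test_that("Greenwood interval matches the single-interval closed form", {
  rows <- data.frame(interval = 0, L_eff = 100, D = 10, CR = 0.9)
  ci <- cr_confidence_interval(rows)
  half <- 1.959963984540054 * sqrt(10 / (100 * 90))
  expect_equal(ci$ci_low, exp(log(0.9) - half), tolerance = 1e-12)
  expect_equal(ci$ci_high, exp(log(0.9) + half), tolerance = 1e-12)
  none <- cr_confidence_interval(data.frame(interval = 0:1, L_eff = c(10, 10),
                                            D = c(0, 0), CR = c(1.01, 1.02)))
  expect_equal(none$ci_low, c(1.01, 1.02))
  expect_equal(none$ci_high, c(1.01, 1.02))
  expect_error(cr_confidence_interval(data.frame(interval = 0, L_eff = 5, D = 5,
                                                 CR = 0.5)), "variance")
})

test_that("Greenwood CI brackets a bootstrap interval on a synthetic cohort", {
  preset <- alswh_like_preset(n = 2000, seed = 31)
  coh <- simulate_cohort(preset$config, preset$table)
  fit <- rs_lifetable(coh, preset$table, max_intervals = 12)
  n_int <- nrow(fit)

  set.seed(99)
  boot_cr <- replicate(1000, {
    bs <- coh[sample.int(nrow(coh), replace = TRUE), ]
    b <- rs_lifetable(bs, preset$table, max_intervals = 12)
    b$CR[n_int]
  })
  boot_ci <- stats::quantile(boot_cr, c(0.025, 0.975), names = FALSE)
  width <- fit$ci_high[n_int] - fit$ci_low[n_int]
  expect_lt(abs(fit$ci_low[n_int] - boot_ci[1]), 0.15 * width)
  expect_lt(abs(fit$ci_high[n_int] - boot_ci[2]), 0.15 * width)
})

test_that("survival ratios are invariant to rescaling all weights", {
  set.seed(11)
  coh <- make_cohort(follow_up = rexp(300, 0.15), event = rbinom(300, 1, 0.5),
                     weight = runif(300, 0.5, 2))
  lt <- flat_lifetable(0.03)
  f1 <- rs_lifetable(coh, lt)
  coh$weight <- coh$weight * 7.3
  f2 <- rs_lifetable(coh, lt)
  for (col in c("P", "CP", "P_star", "CP_star", "R", "CR"))
    expect_equal(f1[[col]], f2[[col]], tolerance = 1e-12)
  expect_equal(f2$L, 7.3 * f1$L, tolerance = 1e-9)
})

test_that("subgroup life tables pool to the total: weighted deaths add up", {
  preset <- alswh_like_preset(n = 3000, seed = 5)
  coh <- simulate_cohort(preset$config, preset$table)
  total <- tabulate_intervals(coh, max_intervals = 12)
  parts <- lapply(split(coh, coh$stratum), tabulate_intervals, max_intervals = 12)
  pooled_D <- Reduce(`+`, lapply(parts, function(p) p$D[match(0:11, p$interval)]))
  expect_equal(pooled_D, total$D, tolerance = 1e-9)
})

test_that("mid-interval censoring keeps the final-interval ratio within its documented approximation error", {
  # with administrative censoring spread uniformly over the final interval,
  # the actuarial convention (half-interval exposure, half q for the
  # censored) is only first-order exact: R carries an upward bias of about
  # mu^2 / 3 (~0.001-0.002 at ages 81-86 here); it must stay below 0.5%
  preset <- alswh_like_preset()
  n_rep <- 50
  r12 <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- scenario_config(n = 5000, entry_year = 1996,
                           healthy_volunteer_factor = 1, horizon = 12,
                           entry_spread = 1, seed = 61000 + r)
    coh <- simulate_cohort(cfg, preset$table)
    fit <- rs_lifetable(coh, preset$table, max_intervals = 12)
    r12[r] <- fit$R[12]
  }
  expect_lt(abs(mean(r12) - 1), 0.005)
})

test_that("a uniformly healthier cohort shows CR above 1 in every interval", {
  preset <- alswh_like_preset(n = 20000, seed = 17)
  cfg <- preset$config
  cfg$beta_truth <- list()
  cfg$covariate_specs <- list()
  cfg$healthy_volunteer_factor <- 0.8
  coh <- simulate_cohort(cfg, preset$table)
  fit <- rs_lifetable(coh, preset$table, max_intervals = 12)
  expect_true(all(fit$CR > 1))
  expect_gt(fit$CR[12], fit$CR[1])
})

test_that("the full life-table object is well formed end to end", {
  preset <- alswh_like_preset(n = 1500, seed = 3)
  coh <- simulate_cohort(preset$config, preset$table)
  fit <- rs_lifetable(coh, preset$table, max_intervals = 12)
  expect_s3_class(fit, "rs_lifetable")
  expect_named(fit, c("interval", "start", "end", "L", "D", "W", "L_eff",
                      "P", "CP", "D_star", "P_star", "CP_star", "R", "CR",
                      "ci_low", "ci_high"))
  expect_true(all(diff(fit$CP) <= 0))         # cumulative survival non-increasing
  expect_true(all(diff(fit$CP_star) <= 0))
  expect_true(all(fit$ci_low <= fit$CR & fit$CR <= fit$ci_high))
  expect_equal(fit$L_eff, fit$L - fit$W / 2)
  s <- summary(fit)
  expect_equal(s$CR, fit$CR[12])
  expect_error(rs_lifetable(counts = data.frame(L = 10, D = 1, W = 0),
                            expected = c(0.9, 0.9)), "intervals")
})
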