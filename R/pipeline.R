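#' Run the relative-survival pipeline end to end
#'
#' Orchestrates the package's stages from a single configuration and writes
#' CSV outputs plus a run log.  Steps (any subset, executed in this order):
#' \describe{
#'   \item{simulate}{generate a synthetic cohort and life table from a
#'     scenario and write them as CSV;}
#'   \item{lifetable}{relative-survival life table (plus optional subgroup
#'     runs via \code{by}), written in the 12-column published layout;}
#'   \item{regress}{multiplicative relative-mortality regression, written as
#'     \code{covariate,level,hazard_ratio,ci_low,ci_high,beta,se};}
#'   \item{compare}{chi-squared comparison of cohort vs reference category
#'     counts, written as
#'     \code{covariate,category,cohort_pct,reference_pct,chi2,df,p}.}
#' }
#'
#' @param config a named list, or the path of a YAML file with the same
#'   keys: \code{steps} (character vector), \code{seed}, \code{width},
#'   \code{weighted}, \code{horizon}, \code{cohort_file},
#'   \code{lifetable_file}, \code{comparison_file}, \code{formula}
#'   (character, e.g. \code{"~ smoking"}), \code{by} (subgroup columns),
#'   \code{scenario} (\code{"default"} or a \code{scenario_config} list for
#'   the simulate step), \code{expected_file} (injected per-interval expected
#'   survival for validation runs).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of the objects produced and the paths
#'   written.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::yaml.load_file(config)
  }
  stopifnot(is.list(config))
  steps <- config$steps
  known <- c("simulate", "lifetable", "regress", "compare")
  if (is.null(steps) || !length(steps)) stop("config$steps is empty")
  if (length(setdiff(steps, known)))
    stop("unknown step(s): ", paste(setdiff(steps, known), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  width <- config$width %||% 1
  weighted <- config$weighted %||% TRUE
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("relsurvgen %s | R %s | %s", as.character(utils::packageVersion("relsurvgen")),
          paste(R.version$major, R.version$minor, sep = "."), format(Sys.time()))
  logline("steps: %s | seed: %s | width: %g | weighted: %s",
          paste(steps, collapse = ","), format(config$seed %||% NA), width, weighted)

  out <- list(paths = character())
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    out$paths <<- c(out$paths, p)
    p
  }

  cohort <- NULL
  lt <- NULL

  if ("simulate" %in% steps) {
    sc <- config$scenario %||% "default"
    if (identical(sc, "default")) {
      preset <- alswh_like_preset(seed = config$seed %||% 1996)
    } else {
      sc$seed <- sc$seed %||% config$seed
      preset <- list(config = do.call(scenario_config, sc),
                     table = alswh_like_preset()$table)
    }
    cohort <- simulate_cohort(preset$config, preset$table)
    lt <- preset$table
    emit(cohort, "cohort.csv")
    emit(as.data.frame(lt), "population_lifetable.csv")
    logline("simulate: n = %d, events = %d", nrow(cohort), sum(cohort$event))
    out$cohort <- cohort
    out$table <- lt
  }

  if (is.null(cohort) && !is.null(config$cohort_file)) {
    cohort <- read_cohort(config$cohort_file)
    logline("cohort: %d records from %s", nrow(cohort), config$cohort_file)
  }
  if (is.null(lt) && !is.null(config$lifetable_file)) {
    lt <- read_lifetable(config$lifetable_file)
    logline("life table: %d cells from %s", nrow(lt), config$lifetable_file)
  }

  if ("lifetable" %in% steps) {
    if (is.null(cohort)) stop("lifetable step needs a cohort (file or simulate step)")
    if (!is.null(config$horizon)) cohort <- censor_at(cohort, config$horizon)
    expected <- NULL
    if (!is.null(config$expected_file))
      expected <- utils::read.csv(config$expected_file)
    if (is.null(expected) && is.null(lt))
      stop("lifetable step needs a population life table or expected_file")
    fit <- rs_lifetable(records = cohort, table = lt, expected = expected,
                        width = width, weighted = weighted,
                        max_intervals = config$max_intervals)
    emit(as.data.frame(fit), "lifetable.csv")
    s <- summary(fit)
    logline("lifetable: CR(%gy) = %.3f (%.3f-%.3f)", s$horizon, s$CR, s$ci[1], s$ci[2])
    out$lifetable <- fit
    for (by in config$by) {
      sub <- rs_lifetable_by(cohort, lt, by, width = width, weighted = weighted,
                             max_intervals = config$max_intervals)
      emit(sub, paste0("lifetable_by_", by, ".csv"))
      out[[paste0("by_", by)]] <- sub
    }
  }

  if ("regress" %in% steps) {
    if (is.null(cohort) || is.null(lt))
      stop("regress step needs a cohort and a population life table")
    if (is.null(config$formula)) stop("regress step needs config$formula")
    fit <- relmort(stats::as.formula(config$formula), cohort, lt,
                   width = width, use_weights = weighted)
    tab <- hazard_ratio_table(fit)
    emit(tab, "regression.csv")
    logline("regress: %d events, converged = %s", fit$n_events, fit$converged)
    out$regression <- fit
  }

  if ("compare" %in% steps) {
    if (is.null(config$comparison_file))
      stop("compare step needs config$comparison_file")
    ct <- read_category_table(config$comparison_file)
    rows <- lapply(split(ct, ct$covariate), function(g) {
      ht <- chi_square_compare(g$cohort_count, g$reference_count)
      data.frame(covariate = g$covariate, category = g$category,
                 cohort_pct = 100 * g$cohort_count / sum(g$cohort_count),
                 reference_pct = 100 * g$reference_count / sum(g$reference_count),
                 chi2 = ht$statistic, df = ht$df, p = ht$p_value)
    })
    cmp <- do.call(rbind, rows)
    rownames(cmp) <- NULL
    emit(cmp, "comparison.csv")
    logline("compare: %d covariates", length(unique(cmp$covariate)))
    out$comparison <- cmp
  }

  logline("done")
  out$paths <- c(out$paths, logf)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
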