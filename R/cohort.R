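#' Read individual-level cohort records
#'
#' A cohort file is a CSV with one row per participant and required columns
#' \code{id, entry_age, entry_year, follow_up, event, weight, stratum}.
#' \code{follow_up} is elapsed years from study entry, \code{event} is the
#' death indicator (1 = died at \code{follow_up}, 0 = censored) and
#' \code{weight} is a positive sampling weight correcting design oversampling
#' (1 for a self-weighting sample).  Any remaining columns are treated as
#' baseline categorical covariates and kept as character columns.
#'
#' @param path path to the cohort CSV.
#' @return A data frame of validated records (possibly zero rows, with a
#'   warning for a header-only file).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("cohort file contains no records: ", path)
    return(validate_cohort(df, allow_empty = TRUE))
  }
  validate_cohort(df)
}

#' Validate cohort records
#'
#' Checks the cohort contract: required columns present, \code{follow_up >= 0},
#' \code{event} in \{0, 1\}, \code{weight > 0}.  Errors name the first
#' offending row.
#'
#' @param records a data frame of cohort records.
#' @param allow_empty logical; accept a zero-row frame.
#' @return The records, with key columns coerced to their canonical types.
#' @export
validate_cohort <- function(records, allow_empty = FALSE) {
  req <- c("id", "entry_age", "entry_year", "follow_up", "event", "weight", "stratum")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("cohort data lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L) {
    if (!allow_empty) stop("cohort is empty")
    return(records)
  }
  records$id <- as.character(records$id)
  records$entry_age <- as.integer(records$entry_age)
  records$entry_year <- as.integer(records$entry_year)
  records$follow_up <- as.numeric(records$follow_up)
  records$event <- as.numeric(records$event)
  records$weight <- as.numeric(records$weight)
  records$stratum <- as.character(records$stratum)

  fail <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("invalid cohort record in row %d (id %s): %s",
                   i[1], records$id[i[1]], what))
  }
  fail(is.na(records$follow_up) | records$follow_up < 0, "follow_up must be >= 0")
  fail(is.na(records$event) | !(records$event %in% c(0, 1)), "event must be 0 or 1")
  fail(is.na(records$weight) | records$weight <= 0, "weight must be > 0")
  fail(is.na(records$entry_age) | is.na(records$entry_year), "entry_age/entry_year must be integers")
  records
}

#' Names of the covariate columns of a cohort
#' @param records a cohort data frame.
#' @return Character vector (possibly empty).
#' @export
cohort_covariates <- function(records) {
  setdiff(names(records),
          c("id", "entry_age", "entry_year", "follow_up", "event", "weight", "stratum"))
}

#' Write cohort records to CSV
#' @param records a cohort data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Administrative censoring at a fixed horizon
#'
#' Records with follow-up beyond \code{horizon} are truncated to
#' \code{horizon} with the event indicator cleared; records at or below the
#' horizon are unchanged.  The number of events can only decrease.
#'
#' @param records a cohort data frame.
#' @param horizon positive number of years.
#' @return The censored records.
#' @export
censor_at <- function(records, horizon) {
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon > 0)
  over <- records$follow_up > horizon
  records$event[over] <- 0
  records$follow_up[over] <- horizon
  records
}

#' Read a cohort-vs-reference category table
#'
#' CSV with columns \code{covariate, category, cohort_count, reference_count}
#' (counts may be weighted).  Rows for one covariate define one comparison
#' table; category order follows file order.
#'
#' @param path path to the CSV.
#' @return A data frame with the four columns above.
#' @export
read_category_table <- function(path) {
  if (!file.exists(path)) stop("category table file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("covariate", "category", "cohort_count", "reference_count")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("category table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(df$cohort_count < 0) || any(df$reference_count < 0))
    stop("category counts must be non-negative")
  df
}
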