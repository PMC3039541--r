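#' Population life tables
#'
#' A \code{poplifetable} stores annual death probabilities \eqn{q_x} from a
#' published population life table, keyed by stratum (e.g. State/Territory or
#' region), calendar year and integer age.  The death probability is the
#' canonical stored quantity, as in national life-table publications; the
#' matching annual survival probability \eqn{p^* = 1 - q} and the
#' piecewise-constant hazard \eqn{\mu^* = -\log(1 - q)} are derived on lookup.
#'
#' Lookups outside the tabulated range are resolved deterministically: ages
#' are clamped to the tabulated age range (published tables end in an
#' open-ended terminal age group), and a calendar year outside the tabulated
#' years maps to the nearest available year for that stratum (ties go to the
#' earlier year).
#'
#' @param x a data frame with one row per (stratum, year, age) cell.
#' @param schema named character vector mapping the roles
#'   \code{c("stratum", "year", "age", "q")} to column names in the input.
#' @return An object of class \code{poplifetable}: a data frame with columns
#'   \code{stratum}, \code{year}, \code{age}, \code{q} and attributes
#'   \code{age_range}, \code{year_range} and \code{strata}.
#' @examples
#' lt <- as_poplifetable(data.frame(
#'   stratum = "S", year = 1996, age = 70:72, qx = c(0.02, 0.03, 0.04)))
#' expected_survival(lt, "S", 1996, 70)   # 0.98
#' expected_hazard(lt, "S", 1996, 70)     # -log(0.98)
#' @export
as_poplifetable <- function(x, schema = c(stratum = "stratum", year = "year",
                                          age = "age", q = "qx")) {
  roles <- c("stratum", "year", "age", "q")
  if (!all(roles %in% names(schema)))
    stop("schema must name columns for: ", paste(roles, collapse = ", "))
  missing_cols <- setdiff(unname(schema[roles]), names(x))
  if (length(missing_cols))
    stop("life-table input lacks column(s): ", paste(missing_cols, collapse = ", "))

  df <- data.frame(stratum = as.character(x[[schema[["stratum"]]]]),
                   year    = as.integer(x[[schema[["year"]]]]),
                   age     = as.integer(x[[schema[["age"]]]]),
                   q       = as.numeric(x[[schema[["q"]]]]),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("life table is empty")
  if (anyNA(df)) stop("life table contains missing values")

  bad <- which(df$q < 0 | df$q >= 1)
  if (length(bad))
    stop(sprintf("death probability out of [0,1) in row %d (stratum %s, year %d, age %d): q = %g",
                 bad[1], df$stratum[bad[1]], df$year[bad[1]], df$age[bad[1]], df$q[bad[1]]))

  key <- paste(df$stratum, df$year, df$age, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (stratum, year, age) cell: ",
         gsub("\r", " / ", d, fixed = TRUE))
  }

  # ages must form one contiguous range, identical in every stratum-year block
  age_range <- range(df$age)
  ages_full <- age_range[1]:age_range[2]
  for (g in split(df$age, paste(df$stratum, df$year, sep = "\r"))) {
    if (!identical(sort(g), ages_full)) {
      gs <- sort(g)
      gap <- if (length(gs) > 1 && any(diff(gs) > 1L))
        gs[which(diff(gs) > 1L)[1]] + 1L else NA_integer_
      stop("ages are not contiguous and uniform across stratum-year blocks",
           if (!is.na(gap)) sprintf(" (age %d missing)", gap) else "")
    }
  }

  df <- df[order(df$stratum, df$year, df$age), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            age_range  = age_range,
            year_range = range(df$year),
            strata     = sort(unique(df$stratum)),
            years_by_stratum = lapply(split(df$year, df$stratum),
                                      function(y) sort(unique(y))),
            class = c("poplifetable", "data.frame"))
}

#' Read a population life table from CSV
#'
#' Expects a header row; the default schema matches columns
#' \code{stratum,year,age,qx}.
#'
#' @param path path to a CSV file.
#' @inheritParams as_poplifetable
#' @return A \code{\link{as_poplifetable}} object.
#' @export
read_lifetable <- function(path, schema = c(stratum = "stratum", year = "year",
                                            age = "age", q = "qx")) {
  if (!file.exists(path)) stop("life-table file not found: ", path)
  as_poplifetable(utils::read.csv(path, stringsAsFactors = FALSE), schema = schema)
}

#' @export
print.poplifetable <- function(x, ...) {
  ar <- attr(x, "age_range"); yr <- attr(x, "year_range")
  cat(sprintf("Population life table: %d cells\n", nrow(x)))
  cat(sprintf("  strata: %s\n", paste(attr(x, "strata"), collapse = ", ")))
  cat(sprintf("  years:  %d-%d   ages: %d-%d\n", yr[1], yr[2], ar[1], ar[2]))
  invisible(x)
}

# Vectorised q lookup with age clamping and nearest-year fallback.
# Arguments are recycled to a common length.
lookup_q <- function(table, stratum, year, age) {
  if (!inherits(table, "poplifetable")) stop("not a poplifetable")
  n <- max(length(stratum), length(year), length(age))
  stratum <- rep_len(as.character(stratum), n)
  year <- rep_len(as.integer(year), n)
  age <- rep_len(as.integer(age), n)

  unknown <- setdiff(unique(stratum), attr(table, "strata"))
  if (length(unknown))
    stop("stratum not present in life table: ", paste(unknown, collapse = ", "))

  ar <- attr(table, "age_range")
  age <- pmin(pmax(age, ar[1]), ar[2])

  # nearest-year fallback per stratum (ties resolve to the earlier year)
  ybs <- attr(table, "years_by_stratum")
  for (s in unique(stratum)) {
    ys <- ybs[[s]]
    idx <- which(stratum == s)
    miss <- idx[!(year[idx] %in% ys)]
    if (length(miss)) {
      nearest <- vapply(year[miss], function(y) ys[which.min(abs(ys - y))], integer(1))
      year[miss] <- nearest
    }
  }

  tkey <- paste(table$stratum, table$year, table$age, sep = "\r")
  m <- match(paste(stratum, year, age, sep = "\r"), tkey)
  if (anyNA(m)) {
    i <- which(is.na(m))[1]
    stop(sprintf("no life-table cell for (stratum %s, year %d, age %d)",
                 stratum[i], year[i], age[i]))
  }
  table$q[m]
}

#' Expected annual survival from a population life table
#'
#' Returns \eqn{p^* = 1 - q} for the resolved (stratum, year, age) cell; this
#' is the probability that a population member of that age, year and stratum
#' survives the next year, used as the expected survival of a matched cohort
#' member.  Arguments are vectorised and recycled.
#'
#' @param table a \code{poplifetable}.
#' @param stratum,year,age lookup keys; ages clamp to the tabulated range and
#'   out-of-range years fall back to the nearest tabulated year.
#' @return Numeric vector of annual survival probabilities.
#' @seealso \code{\link{expected_hazard}}
#' @export
expected_survival <- function(table, stratum, year, age) {
  1 - lookup_q(table, stratum, year, age)
}

#' Expected annual hazard from a population life table
#'
#' Returns \eqn{\mu^* = -\log(1 - q)}, the constant hazard over one year of
#' age consistent with the annual death probability \eqn{q}, so that
#' \code{exp(-expected_hazard(...)) == expected_survival(...)} exactly.  This
#' is the population mortality intensity used as the known baseline of the
#' multiplicative relative-mortality model.
#'
#' @inheritParams expected_survival
#' @return Numeric vector of hazards (per year).
#' @export
expected_hazard <- function(table, stratum, year, age) {
  -log1p(-lookup_q(table, stratum, year, age))
}
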