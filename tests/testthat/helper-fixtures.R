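# Fixtures are built in code; nothing is read from disk except the published
# aggregate tables shipped under inst/extdata.

# life table with one constant annual death probability everywhere
flat_lifetable <- function(q = 0.02, strata = "S", years = 1994:2010,
                           ages = 60:100) {
  grid <- expand.grid(stratum = strata, year = years, age = ages,
                      stringsAsFactors = FALSE)
  grid$qx <- q
  as_poplifetable(grid)
}

# minimal cohort data frame; extra named arguments become covariate columns
make_cohort <- function(follow_up, event, weight = 1, entry_age = 70,
                        entry_year = 1996, stratum = "S", ...) {
  n <- length(follow_up)
  df <- data.frame(id = sprintf("r%03d", seq_len(n)),
                   entry_age = entry_age, entry_year = entry_year,
                   follow_up = follow_up, event = event,
                   weight = weight, stratum = stratum,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (v in names(extra)) df[[v]] <- extra[[v]]
  df
}

# independent brute-force life-table tabulation: explicit loop over records
# and intervals, no vectorisation shared with the implementation
brute_force_tabulate <- function(records, width = 1, weighted = TRUE) {
  w <- if (weighted) records$weight else rep(1, nrow(records))
  n_int <- max(floor(records$follow_up / width)) + 1L
  L <- D <- W <- numeric(n_int)
  for (i in seq_len(n_int)) {
    start <- (i - 1) * width
    for (j in seq_len(nrow(records))) {
      fu <- records$follow_up[j]
      if (fu >= start) {
        # still under observation at the interval start (endpoint at the
        # boundary belongs to the interval starting there)
        if (floor(fu / width) >= i - 1) L[i] <- L[i] + w[j]
        if (floor(fu / width) == i - 1) {
          if (records$event[j] == 1) D[i] <- D[i] + w[j]
          else W[i] <- W[i] + w[j]
        }
      }
    }
  }
  data.frame(interval = seq_len(n_int) - 1L, L = L, D = D, W = W)
}

# published 12-interval cohort life table (aggregate counts + expected
# survival) shipped with the package
published_lifetable_counts <- function() {
  path <- system.file("extdata", "alswh_1921_26_lifetable.csv",
                      package = "relsurvgen")
  t1 <- utils::read.csv(path)
  list(counts = data.frame(interval = seq_len(nrow(t1)) - 1L,
                           start = t1$interval_start, end = t1$interval_end,
                           L = t1$L, D = t1$D, W = t1$W),
       expected = t1[, c("P_star", "CP_star")])
}
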