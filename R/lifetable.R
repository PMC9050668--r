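#' Stratum eligibility rule for life-table publication
#'
#' A stratum qualifies for a published life table only when every closed
#' one-year interval contains at least `min_per_interval` deaths and the open
#' final interval contains at least `min_last_interval` deaths. The defaults
#' (3 and 11) ensure that the per-interval mean fraction of the last year
#' lived is an average over more than one animal, and that the tail of the
#' table, which every life expectancy depends on, is estimated from a
#' non-trivial number of deaths.
#'
#' @param min_per_interval minimum deaths in each closed one-year interval.
#' @param min_last_interval minimum deaths pooled into the open final interval.
#' @return an object of class `eligibility_rule`.
#' @export
eligibility_rule <- function(min_per_interval = 3L, min_last_interval = 11L) {
  min_per_interval <- as.integer(min_per_interval)
  min_last_interval <- as.integer(min_last_interval)
  if (is.na(min_per_interval) || min_per_interval < 1L)
    stop_config("min_per_interval must be an integer >= 1")
  if (is.na(min_last_interval) || min_last_interval < 1L)
    stop_config("min_last_interval must be an integer >= 1")
  structure(list(min_per_interval = min_per_interval,
                 min_last_interval = min_last_interval),
            class = "eligibility_rule")
}

#' Assign lifespans to one-year age intervals
#'
#' Each lifespan t (in years) falls in the half-open interval [x, x + 1) with
#' x = floor(t), so integer lifespans carry a within-interval fraction of 0.
#'
#' @param lifespans numeric vector of non-negative lifespans in years.
#' @return a named list mapping each age x (as a name, ages with deaths only)
#'   to the vector of within-interval fractions t - x.
#' @export
assign_intervals <- function(lifespans) {
  if (length(lifespans) == 0) return(structure(list(), names = character(0)))
  if (anyNA(lifespans)) stop_data("lifespans contain missing values")
  if (any(lifespans < 0)) stop_data("negative lifespans are not allowed here; cleaning should have removed them")
  x <- floor(lifespans)
  split(lifespans - x, x)
}

#' Choose the start of the open final interval
#'
#' The open row "n and over" starts at the largest age x whose tail death
#' count (deaths at ages >= x) still meets the last-interval minimum; all
#' deaths at ages >= n pool into it. If, in addition, any closed interval
#' below n holds fewer than `min_per_interval` deaths, the stratum is flagged
#' ineligible (but n is still reported when it exists).
#'
#' @param counts integer vector of deaths per age; either named by age or
#'   positional from age 0.
#' @param rule an [eligibility_rule()].
#' @return list with `n` (integer, or `NA` when the total death count cannot
#'   support an open interval), `eligible` (logical) and `reasons`
#'   (character vector, empty when eligible).
#' @export
choose_final_interval <- function(counts, rule = eligibility_rule()) {
  if (length(counts) == 0) stop_data("empty death counts")
  d <- complete_counts(counts)
  ages <- as.integer(names(d))
  tails <- revcumsum(d)
  ok <- which(tails >= rule$min_last_interval)
  if (length(ok) == 0) {
    return(list(n = NA_integer_,
                eligible = FALSE,
                reasons = sprintf("total deaths (%d) below the last-interval minimum (%d)",
                                  sum(d), rule$min_last_interval)))
  }
  n <- ages[max(ok)]
  reasons <- character(0)
  if (n > 0) {
    closed <- d[ages < n]
    short <- which(closed < rule$min_per_interval)
    if (length(short) > 0) {
      reasons <- sprintf("closed interval(s) %s hold fewer than %d deaths",
                         paste(ages[short], collapse = ", "), rule$min_per_interval)
    }
  }
  list(n = n, eligible = length(reasons) == 0, reasons = reasons)
}

# expand a possibly-named, possibly-sparse count vector into a dense vector
# over ages 0..max(age), named by age
complete_counts <- function(counts) {
  if (is.null(names(counts))) {
    ages <- seq_along(counts) - 1L
  } else {
    ages <- as.integer(names(counts))
    if (anyNA(ages)) stop_data("count names must be integer ages")
  }
  if (any(counts < 0)) stop_data("negative death counts")
  dense <- integer(max(ages) + 1L)
  dense[ages + 1L] <- as.integer(round(counts))
  names(dense) <- 0:max(ages)
  dense
}

#' Build a cohort life table from individual lifespans
#'
#' Tabulates deaths into one-year intervals, chooses the open final interval
#' under `rule`, and derives the standard columns: deaths d, survivors l,
#' interval death probability q = d / l, mean fraction of the last year lived
#' a (for the open row, mean years lived past its start), dog-years lived in
#' the interval L = (l - d) + a d (open row: a d), dog-years lived beyond x
#' T, and life expectancy e = T / l. The final row is open ("n and over"):
#' its l equals its d, its q is 1 and its e equals its a.
#'
#' Ineligible strata are returned as a table flagged `eligible = FALSE`
#' rather than raising, so callers (in particular the bootstrap) can assess
#' eligibility without exceptions as control flow.
#'
#' @param lifespans numeric vector of non-negative lifespans in years.
#' @param rule an [eligibility_rule()].
#' @param stratum named character vector labelling the stratum
#'   (e.g. `c(scheme = "sex", label = "female")`).
#' @return an object of class `life_table`; see [life_table_rows()].
#' @export
build_life_table <- function(lifespans, rule = eligibility_rule(),
                             stratum = c(scheme = "overall", label = "overall")) {
  if (length(lifespans) == 0) stop_data("cannot build a life table from an empty cohort")
  if (anyNA(lifespans)) stop_data("lifespans contain missing values")
  if (any(lifespans < 0)) stop_data("negative lifespans are not allowed here")
  x <- floor(lifespans)
  maxage <- max(x)
  d <- as.integer(tabulate(x + 1L, nbins = maxage + 1L))
  rs <- rowsum(lifespans - x, x)
  sumfrac <- numeric(maxage + 1L)
  sumfrac[as.integer(rownames(rs)) + 1L] <- rs[, 1L]
  names(d) <- 0:maxage
  fin <- choose_final_interval(d, rule)
  if (is.na(fin$n)) {
    # too few deaths for any open interval: pool everything at age 0
    n <- 0L
  } else {
    n <- fin$n
  }
  lt_from_interval_stats(d, sumfrac, n = n, eligible = isTRUE(fin$eligible) && !is.na(fin$n),
                         reasons = fin$reasons, stratum = stratum, rule = rule)
}

# shared constructor: d and sumfrac are dense over ages 0..maxage;
# deaths at ages >= n pool into the open final row
lt_from_interval_stats <- function(d, sumfrac, n, eligible, reasons, stratum, rule) {
  maxage <- length(d) - 1L
  stopifnot(n <= maxage)
  idx_open <- (n + 1L):(maxage + 1L)      # ages n..maxage pool into open row
  d_open <- sum(d[idx_open])
  # mean years lived past n by the open row's members
  ages <- 0:maxage
  a_open <- (sum(sumfrac[idx_open]) + sum((ages[idx_open] - n) * d[idx_open])) / d_open
  if (n > 0) {
    dd <- c(d[1:n], d_open)
    aa <- c(ifelse(d[1:n] > 0, sumfrac[1:n] / d[1:n], NA_real_), a_open)
  } else {
    dd <- d_open
    aa <- a_open
  }
  tab <- derive_columns(dd, aa)
  new_life_table(tab, stratum = stratum, final_open_start = as.integer(n),
                 eligible = eligible, reasons = reasons, rule = rule)
}

# derive l, q, L, T, e from deaths and mean-fraction-lived; last row is open
derive_columns <- function(d, a_hat) {
  d <- unname(d)
  a_hat <- unname(a_hat)
  k <- length(d)
  l <- revcumsum(d)
  q_hat <- ifelse(l > 0, d / l, NA_real_)
  L <- (l - d) + ifelse(d > 0, a_hat * d, 0)
  L[k] <- a_hat[k] * d[k]
  Tx <- revcumsum(L)
  e_hat <- Tx / l
  data.frame(x = 0:(k - 1L), d = as.integer(d), l = as.integer(l),
             q_hat = q_hat, a_hat = a_hat, L = L, T = Tx, e_hat = e_hat,
             e_lo = NA_real_, e_hi = NA_real_)
}

new_life_table <- function(rows, stratum, final_open_start, eligible,
                           reasons = character(0), rule = eligibility_rule()) {
  structure(list(rows = rows,
                 stratum = stratum,
                 final_open_start = final_open_start,
                 eligible = eligible,
                 reasons = reasons,
                 rule = rule,
                 n_animals = as.integer(rows$l[1])),
            class = "life_table")
}

#' Build a life table from pre-tabulated aggregates
#'
#' Takes the per-interval death counts and mean fractions of the last year
#' lived (with the final entry describing the open interval) and derives the
#' remaining columns exactly as [build_life_table()] does. This is the path
#' for reproducing a published table from its printed aggregate columns.
#'
#' @param d integer vector of deaths for ages 0..n, the last entry being the
#'   open "n and over" row.
#' @param a_hat numeric vector, same length as `d`: mean fraction of the last
#'   year lived per closed interval, and for the last entry the mean years
#'   lived past n. May be `NA` only where `d` is 0.
#' @param stratum named character vector labelling the stratum.
#' @param rule an [eligibility_rule()] used to flag eligibility.
#' @return an object of class `life_table`.
#' @export
build_from_aggregates <- function(d, a_hat,
                                  stratum = c(scheme = "overall", label = "overall"),
                                  rule = eligibility_rule()) {
  if (length(d) != length(a_hat))
    stop_data(sprintf("length mismatch: %d death counts vs %d a_hat values",
                      length(d), length(a_hat)))
  if (length(d) == 0) stop_data("empty aggregate table")
  if (any(d < 0)) stop_data("negative death counts")
  if (any(d > 0 & is.na(a_hat)))
    stop_data("a_hat missing for interval(s) with deaths")
  k <- length(d)
  if (d[k] == 0) stop_data("the open final interval must contain deaths")
  if (any(!is.na(a_hat[-k]) & (a_hat[-k] < 0 | a_hat[-k] >= 1)))
    stop_data("closed-interval a_hat values must lie in [0, 1)")
  if (a_hat[k] < 0) stop_data("open-interval a_hat must be non-negative")
  n <- k - 1L
  closed_ok <- n == 0 || all(d[1:n] >= rule$min_per_interval)
  open_ok <- d[k] >= rule$min_last_interval
  reasons <- character(0)
  if (!closed_ok) reasons <- c(reasons, "closed interval(s) below the per-interval minimum")
  if (!open_ok) reasons <- c(reasons, "open interval below the last-interval minimum")
  tab <- derive_columns(as.integer(d), as.numeric(a_hat))
  new_life_table(tab, stratum = stratum, final_open_start = n,
                 eligible = length(reasons) == 0, reasons = reasons, rule = rule)
}

#' Life-table rows
#'
#' @param table a `life_table`.
#' @return the data frame of rows: `x`, `d`, `l`, `q_hat`, `a_hat`, `L`, `T`,
#'   `e_hat`, `e_lo`, `e_hi` (bounds `NA` until a bootstrap attaches them).
#' @export
life_table_rows <- function(table) {
  stopifnot(inherits(table, "life_table"))
  table$rows
}

#' Life expectancy at given ages
#'
#' @param table a `life_table`.
#' @param ages integer ages; ages beyond the table return `NA`.
#' @return numeric vector of life expectancies (years).
#' @export
life_expectancy <- function(table, ages = 0L) {
  stopifnot(inherits(table, "life_table"))
  table$rows$e_hat[match(ages, table$rows$x)]
}

#' @export
print.life_table <- function(x, ...) {
  lab <- paste(sprintf("%s=%s", names(x$stratum), x$stratum), collapse = ", ")
  cat(sprintf("Cohort life table [%s]: %d animals, ages 0-%d%s, %s\n",
              lab, x$n_animals, x$final_open_start, " (final interval open)",
              if (x$eligible) "eligible" else
                paste0("INELIGIBLE: ", paste(x$reasons, collapse = "; "))))
  print(format_life_table_report(x), row.names = FALSE)
  invisible(x)
}

# internal invariant check used by tests and the writers
validate_life_table <- function(table) {
  r <- table$rows
  k <- nrow(r)
  stopifnot(
    all(r$x == 0:(k - 1L)),
    all(r$d >= 0), all(r$l >= r$d),
    r$l[k] == r$d[k],
    isTRUE(all.equal(r$q_hat[k], 1)),
    isTRUE(all.equal(r$l[1], sum(r$d))),
    all(abs(r$l[-k] - r$d[-k] - r$l[-1]) == 0),
    isTRUE(all.equal(r$e_hat[k], r$a_hat[k])),
    isTRUE(all.equal(r$e_hat, r$T / r$l))
  )
  invisible(TRUE)
}
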