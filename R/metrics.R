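#' Earliest age at which life expectancy drops below a threshold
#'
#' Scans the table from age 0 upwards and reports the first interval
#' [x, x + 1) whose life expectancy is strictly below the threshold
#' ("dropped below": a value exactly at the threshold does not cross).
#'
#' @param table a `life_table`.
#' @param threshold years, default 1.5.
#' @return object of class `threshold_crossing`: `threshold`, `interval`
#'   (integer x, or `NA`), `status` (`"crossed"`, `"at_zero"` when the very
#'   first row is already below, or `"never"`).
#' @export
age_when_e_below <- function(table, threshold = 1.5) {
  stopifnot(inherits(table, "life_table"))
  hit <- which(table$rows$e_hat < threshold)
  if (length(hit) == 0) {
    out <- list(threshold = threshold, interval = NA_integer_, status = "never")
  } else {
    x <- table$rows$x[min(hit)]
    out <- list(threshold = threshold, interval = x,
                status = if (x == 0) "at_zero" else "crossed")
  }
  structure(out, class = "threshold_crossing")
}

#' @export
print.threshold_crossing <- function(x, ...) {
  what <- switch(x$status,
                 never = "never drops below",
                 at_zero = "is already below at age 0 (interval 0-1), threshold",
                 crossed = sprintf("first drops below, in interval %d-%d, the threshold of",
                                   x$interval, x$interval + 1L))
  cat(sprintf("Life expectancy %s %.3g years\n", what, x$threshold))
  invisible(x)
}

#' Compare life tables across strata
#'
#' One row per stratum: life expectancy at age 0 (with rank, 1 = longest)
#' and at each requested age (`NA` beyond the table), the last age in the
#' table and the life expectancy there, and the threshold-crossing interval.
#' Output row order follows the given label order but every column is
#' invariant to it.
#'
#' @param tables named list of eligible `life_table`s.
#' @param ages integer ages at which to report life expectancy.
#' @param threshold passed to [age_when_e_below()].
#' @return a data frame, one row per stratum.
#' @export
compare_strata <- function(tables, ages = c(0L, 5L, 10L), threshold = 1.5) {
  stopifnot(length(tables) > 0, !is.null(names(tables)))
  rows <- lapply(names(tables), function(lab) {
    lt <- tables[[lab]]
    stopifnot(inherits(lt, "life_table"))
    e_at <- life_expectancy(lt, ages)
    names(e_at) <- paste0("e_", ages)
    last_age <- lt$final_open_start
    cr <- age_when_e_below(lt, threshold)
    cbind(data.frame(label = lab, n_animals = lt$n_animals,
                     e_0 = life_expectancy(lt, 0L)),
          as.data.frame(as.list(e_at)),
          data.frame(last_age = last_age,
                     e_last = life_expectancy(lt, last_age),
                     e_below_threshold_interval = cr$interval))
  })
  out <- do.call(rbind, rows)
  out$e0_rank <- as.integer(rank(-out$e_0, ties.method = "min"))
  out
}

#' Demographic summary of a cohort
#'
#' Counts and 1-decimal percentages by sex, neuter status and, when the
#' breed-derived columns are present, purity and breed group. Within each
#' variable the percentages are taken over the animals carrying any value
#' for it (so they sum to 100 up to rounding).
#'
#' @param cohort a cohort data frame.
#' @return a data frame with columns `variable`, `level`, `n`, `pct`.
#' @export
demography_summary <- function(cohort) {
  vars <- intersect(c("sex", "neuter_status", "purity", "kc_group"), names(cohort))
  out <- list()
  for (v in vars) {
    x <- cohort[[v]]
    x <- x[!is.na(x) & nzchar(x)]
    if (length(x) == 0) next
    tab <- table(x)
    out[[v]] <- data.frame(variable = v, level = names(tab),
                           n = as.integer(tab),
                           pct = round(100 * as.integer(tab) / length(x), 1))
  }
  if (length(out) == 0)
    return(data.frame(variable = character(0), level = character(0),
                      n = integer(0), pct = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
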