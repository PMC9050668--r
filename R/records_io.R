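canonical_columns <- c("animal_id", "breed", "sex", "neuter_status",
                       "birth_date", "death_date", "death_mechanism",
                       "clinical_note", "treatment_text", "insured")
mandatory_columns <- c("animal_id", "breed", "sex", "neuter_status",
                       "birth_date", "death_date")

#' CSV dialect for registry files
#'
#' The canonical dialect expects the canonical header names and ISO-8601
#' dates. Files from other systems are read by supplying a mapping from
#' canonical names to the file's header names and, if needed, an explicit
#' date format. Dates are never guessed from locale: a non-ISO file without
#' an explicit format simply yields absent dates with warnings.
#'
#' @param mapping named character vector, canonical name -> file column name.
#' @param date_format a [strptime()] format string, default ISO-8601.
#' @return an object of class `records_dialect`.
#' @export
records_dialect <- function(mapping = character(0), date_format = "%Y-%m-%d") {
  structure(list(mapping = mapping, date_format = date_format),
            class = "records_dialect")
}

#' Read individual death records
#'
#' Reads one record per row. Unparseable dates become absent (with one
#' warning summarising how many), because date problems are a cleaning
#' concern, not a read failure. Missing breed or stratum information is kept
#' as the sentinel `"unknown"`/empty rather than dropped: exclusion is the
#' cohort builder's job. A short read report is emitted as a message and
#' attached as the `"read_report"` attribute.
#'
#' @param path CSV file path.
#' @param dialect a [records_dialect()].
#' @return a `data.frame` of class `death_records` with the canonical columns.
#' @export
read_records <- function(path, dialect = records_dialect()) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         comment.char = "#")
  out <- data.frame(row.names = seq_len(nrow(raw)))
  n_date_warn <- 0L
  for (cc in canonical_columns) {
    file_col <- unname(dialect$mapping[cc])
    if (is.na(file_col) || is.null(file_col)) file_col <- cc
    if (!file_col %in% names(raw)) {
      if (cc %in% mandatory_columns)
        stop_config(sprintf("missing mandatory column '%s' (mapped from '%s')",
                            file_col, cc))
      out[[cc]] <- switch(cc,
                          death_mechanism = rep("unrecorded", nrow(raw)),
                          insured = rep(NA, nrow(raw)),
                          rep("", nrow(raw)))
      next
    }
    out[[cc]] <- raw[[file_col]]
  }
  dup <- unique(out$animal_id[duplicated(out$animal_id)])
  if (length(dup) > 0)
    stop_data(sprintf("duplicate animal_id(s): %s", paste(dup, collapse = ", ")))
  if (any(!nzchar(out$animal_id)))
    stop_data("empty animal_id in input")
  for (dc in c("birth_date", "death_date")) {
    parsed <- parse_date_strict(out[[dc]], dialect$date_format)
    bad <- nzchar(trimws(out[[dc]])) & is.na(parsed)
    if (any(bad)) {
      n_date_warn <- n_date_warn + sum(bad)
      warning(sprintf("%d unparseable %s value(s) set to absent (e.g. id %s)",
                      sum(bad), dc, out$animal_id[which(bad)[1]]), call. = FALSE)
    }
    out[[dc]] <- parsed
  }
  out$sex <- normalise_level(out$sex, c("female", "male"), "unknown")
  out$neuter_status <- normalise_level(out$neuter_status, c("neutered", "entire"), "unknown")
  out$death_mechanism <- normalise_level(out$death_mechanism,
                                         c("euthanased", "unassisted"), "unrecorded")
  out$insured <- parse_optional_logical(out$insured)
  class(out) <- c("death_records", "data.frame")
  report <- list(n = nrow(out), date_warnings = n_date_warn)
  attr(out, "read_report") <- report
  message(sprintf("read %d record(s) from %s (%d date warning(s))",
                  report$n, path, report$date_warnings))
  out
}

normalise_level <- function(x, levels, sentinel) {
  x <- tolower(trimws(as.character(x)))
  x[!nzchar(x) | is.na(x)] <- sentinel
  bad <- !x %in% c(levels, sentinel)
  if (any(bad)) {
    warning(sprintf("%d unrecognised value(s) mapped to '%s': %s", sum(bad),
                    sentinel, paste(unique(x[bad]), collapse = ", ")),
            call. = FALSE)
    x[bad] <- sentinel
  }
  x
}

parse_optional_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1")] <- TRUE
  out[x %in% c("FALSE", "F", "0")] <- FALSE
  out
}

#' Write individual death records in the canonical dialect
#'
#' @param records a `death_records` data frame (or compatible).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_records <- function(records, path) {
  out <- as.data.frame(records)[, canonical_columns]
  for (dc in c("birth_date", "death_date")) {
    v <- out[[dc]]
    out[[dc]] <- ifelse(is.na(v), "", format(as.Date(v), "%Y-%m-%d"))
  }
  out$insured <- ifelse(is.na(out$insured), "", ifelse(out$insured, "TRUE", "FALSE"))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a life table from its printed aggregate columns
#'
#' Reads a CSV holding per-interval death counts `d` and mean fractions of
#' the last year lived `a_hat` (final row open) and rebuilds the full table
#' from those two columns alone. If the file also carries derived columns
#' (`l`, `q_hat`, `L`, `T`, `e_hat`) they are compared against the
#' recomputation and mismatches beyond tolerance are reported as messages,
#' never trusted.
#'
#' @param path CSV with columns `x_start`, `d`, `a_hat` (others optional).
#' @param stratum named character vector labelling the stratum.
#' @param rule an [eligibility_rule()].
#' @param check_tol absolute tolerances for optional derived columns.
#' @return an object of class `life_table`.
#' @export
read_aggregate_table <- function(path,
                                 stratum = c(scheme = "overall", label = "overall"),
                                 rule = eligibility_rule(),
                                 check_tol = c(l = 0, q_hat = 0.0005,
                                               L = 25, T = 150, e_hat = 0.01)) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#")
  for (col in c("x_start", "d")) {
    if (!col %in% names(df))
      stop_config(sprintf("aggregate table is missing column '%s'", col))
  }
  if (!"a_hat" %in% names(df))
    stop_config("aggregate table is missing column 'a_hat'")
  if (!identical(as.integer(df$x_start), seq(0L, nrow(df) - 1L)))
    stop_data("ages (x_start) must be contiguous from 0")
  if (any(df$d < 0)) stop_data("negative death counts in aggregate table")
  lt <- build_from_aggregates(df$d, df$a_hat, stratum = stratum, rule = rule)
  for (col in intersect(c("l", "q_hat", "L", "T", "e_hat"), names(df))) {
    dev <- max(abs(df[[col]] - lt$rows[[col]]), na.rm = TRUE)
    if (dev > check_tol[[col]])
      message(sprintf("provided column '%s' deviates from recomputation by up to %g",
                      col, dev))
  }
  lt
}

#' Write a life table
#'
#' The data rendering keeps full double precision so that
#' `read_life_table(write_life_table(x))` is lossless. A companion report
#' rendering (3-decimal probabilities, 2-decimal years, printed-style
#' interval labels and CI column) is written when `report_path` is given.
#' Header comment lines (`# ...`) carry stratum and provenance metadata.
#'
#' @param table a `life_table`.
#' @param path output CSV path (data rendering).
#' @param report_path optional path for the human-readable rendering.
#' @param header extra header comment lines (without the leading `#`).
#' @return invisibly, `path`.
#' @export
write_life_table <- function(table, path, report_path = NULL, header = character(0)) {
  stopifnot(inherits(table, "life_table"))
  if (nrow(table$rows) == 0) stop_data("refusing to write an empty life table")
  validate_life_table(table)
  r <- table$rows
  k <- nrow(r)
  meta <- c(sprintf("stratum %s", paste(sprintf("%s=%s", names(table$stratum),
                                                table$stratum), collapse = ";")),
            sprintf("final_open_start %d", table$final_open_start),
            sprintf("eligible %s", table$eligible),
            sprintf("rule min_per_interval=%d min_last_interval=%d",
                    table$rule$min_per_interval, table$rule$min_last_interval),
            header)
  x_end <- c(r$x[-k] + 1L, NA_integer_)
  body <- data.frame(x_start = r$x, x_end = x_end, d = r$d, l = r$l,
                     q_hat = format_full(r$q_hat), a_hat = format_full(r$a_hat),
                     L = format_full(r$L), T = format_full(r$T),
                     e_hat = format_full(r$e_hat), e_lo = format_full(r$e_lo),
                     e_hi = format_full(r$e_hi))
  lines <- c(paste0("# ", meta),
             paste(names(body), collapse = ","),
             do.call(paste, c(lapply(body, function(col) {
               col <- as.character(col)
               col[is.na(col)] <- ""
               col
             }), sep = ",")))
  writeLines(lines, path)
  if (!is.null(report_path)) {
    rep <- format_life_table_report(table)
    utils::write.csv(rep, report_path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Human-readable rendering of a life table
#'
#' Probabilities to 3 decimals and years to 2 decimals, with the printed
#' interval notation ("0-1", ..., "n and over") and a combined CI column.
#'
#' @param table a `life_table`.
#' @return a data frame of formatted character columns.
#' @export
format_life_table_report <- function(table) {
  r <- table$rows
  k <- nrow(r)
  interval <- c(sprintf("%d-%d", r$x[-k], r$x[-k] + 1L),
                sprintf("%d and over", r$x[k]))
  ci <- ifelse(is.na(r$e_lo) | is.na(r$e_hi), "",
               sprintf("(%s-%s)", fmt_num(r$e_lo, 2), fmt_num(r$e_hi, 2)))
  data.frame(interval = interval, d = r$d, l = r$l,
             q_hat = fmt_num(r$q_hat, 3), a_hat = fmt_num(r$a_hat, 2),
             L = fmt_num(r$L, 2), T = fmt_num(r$T, 2),
             e_hat = fmt_num(r$e_hat, 2), e_ci = ci)
}

#' Read a life table written by [write_life_table()]
#'
#' @param path CSV path (the data rendering).
#' @return an object of class `life_table`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  all_lines <- readLines(path)
  meta <- sub("^# ", "", grep("^#", all_lines, value = TRUE))
  df <- utils::read.csv(text = paste(grep("^#", all_lines, value = TRUE,
                                          invert = TRUE), collapse = "\n"))
  stratum <- c(scheme = "overall", label = "overall")
  sm <- grep("^stratum ", meta, value = TRUE)
  if (length(sm) == 1) {
    kv <- strsplit(strsplit(sub("^stratum ", "", sm[1]), ";")[[1]], "=")
    stratum <- vapply(kv, `[`, character(1), 2)
    names(stratum) <- vapply(kv, `[`, character(1), 1)
  }
  eligible <- any(grepl("^eligible TRUE", meta))
  rl <- grep("^rule ", meta, value = TRUE)
  rule <- eligibility_rule()
  if (length(rl) == 1) {
    nums <- as.integer(regmatches(rl, gregexpr("[0-9]+", rl))[[1]])
    if (length(nums) == 2) rule <- eligibility_rule(nums[1], nums[2])
  }
  rows <- data.frame(x = as.integer(df$x_start), d = as.integer(df$d),
                     l = as.integer(df$l), q_hat = as.numeric(df$q_hat),
                     a_hat = as.numeric(df$a_hat), L = as.numeric(df$L),
                     T = as.numeric(df$T), e_hat = as.numeric(df$e_hat),
                     e_lo = as.numeric(df$e_lo), e_hi = as.numeric(df$e_hi))
  new_life_table(rows, stratum = stratum,
                 final_open_start = rows$x[nrow(rows)],
                 eligible = eligible, rule = rule)
}
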