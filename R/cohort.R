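#' Observation window for death inclusion
#'
#' Only animals whose death date falls inside the window enter the cohort.
#' The default window is 2016-01-01 to 2020-07-31.
#'
#' @param start,end calendar dates (or ISO strings).
#' @return an object of class `inclusion_window`.
#' @export
inclusion_window <- function(start = "2016-01-01", end = "2020-07-31") {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop_config("window dates must be valid")
  if (start > end) stop_config("window start must not be after its end")
  structure(list(start = start, end = end), class = "inclusion_window")
}

#' Fractional lifespan in years
#'
#' Day count between birth and death divided by 365.25 (leap-safe
#' epidemiological convention). May be negative; cleaning removes such
#' records.
#'
#' @param birth,death `Date` vectors.
#' @return numeric years (`NA` where either date is absent).
#' @export
compute_lifespan <- function(birth, death) {
  as.numeric(as.Date(death) - as.Date(birth)) / 365.25
}

exclusion_reasons <- c("outside_window", "negative_lifespan",
                       "missing_birth_or_death", "missing_sex")

#' Apply cohort inclusion filters
#'
#' Cleans a record set into analysis-ready cohort observations. Records are
#' excluded, with the first applicable reason in this fixed order:
#' (a) death date recorded outside the window, (b) negative lifespan,
#' (c) missing birth or death date, (d) missing sex. Exclusion counts plus
#' inclusions always reconcile to the input size.
#'
#' @param records a `death_records` data frame.
#' @param window an [inclusion_window()].
#' @return list with `cohort` (data frame: `animal_id`, `lifespan_years`,
#'   `sex`, `neuter_status`, `breed`) and `exclusions` (list with `counts`
#'   per reason and a per-record `reasons` data frame).
#' @export
apply_inclusion_filters <- function(records, window = inclusion_window()) {
  n <- nrow(records)
  lifespan <- compute_lifespan(records$birth_date, records$death_date)
  reason <- rep(NA_character_, n)
  has_death <- !is.na(records$death_date)
  has_birth <- !is.na(records$birth_date)
  out_window <- has_death & (records$death_date < window$start |
                             records$death_date > window$end)
  reason[is.na(reason) & out_window] <- "outside_window"
  neg <- has_death & has_birth & lifespan < 0
  reason[is.na(reason) & neg] <- "negative_lifespan"
  reason[is.na(reason) & (!has_death | !has_birth)] <- "missing_birth_or_death"
  reason[is.na(reason) & records$sex == "unknown"] <- "missing_sex"
  keep <- is.na(reason)
  cohort <- data.frame(animal_id = records$animal_id[keep],
                       lifespan_years = lifespan[keep],
                       sex = records$sex[keep],
                       neuter_status = records$neuter_status[keep],
                       breed = records$breed[keep],
                       stringsAsFactors = FALSE)
  counts <- vapply(exclusion_reasons, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  stopifnot(sum(counts) + nrow(cohort) == n)
  excl <- data.frame(animal_id = records$animal_id[!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  list(cohort = cohort,
       exclusions = list(counts = counts, reasons = excl, n_input = n,
                         n_included = nrow(cohort)))
}

#' Read a breed classifier configuration
#'
#' YAML with a `recognised_breeds` list (breeds counted as purebred) and a
#' `groups` map from breed to kennel-club breed group. A compact
#' configuration covering common breeds ships with the package.
#'
#' @param path YAML path; defaults to the packaged configuration.
#' @return list with `recognised` (character) and `groups` (named character).
#' @export
read_breed_classifier <- function(path = system.file("extdata", "breed_classifier.yaml",
                                                     package = "canlife")) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_config(sprintf("malformed breed classifier config: %s", conditionMessage(e))))
  if (is.null(cfg$recognised_breeds) || is.null(cfg$groups))
    stop_config("breed classifier config must define recognised_breeds and groups")
  groups <- unlist(cfg$groups)
  list(recognised = tolower(trimws(as.character(cfg$recognised_breeds))),
       groups = stats::setNames(as.character(groups), tolower(trimws(names(groups)))))
}

#' Classify breeds as purebred/crossbred and into breed groups
#'
#' A breed on the recognised list is purebred; a purebred breed absent from
#' the group map is labelled `"non-KC recognised"`; any other non-empty
#' breed string is crossbred; an empty breed is unrecorded. Matching is
#' case-insensitive on trimmed names.
#'
#' @param breed character vector of breed strings.
#' @param lookup a [read_breed_classifier()] result.
#' @return data frame with columns `purity`
#'   (purebred/crossbred/unrecorded) and `kc_group` (group label,
#'   `"non-KC recognised"`, or `NA` when not applicable).
#' @export
classify_breed <- function(breed, lookup = read_breed_classifier()) {
  key <- tolower(trimws(as.character(breed)))
  recorded <- !is.na(key) & nzchar(key)
  recognised <- recorded & key %in% lookup$recognised
  purity <- ifelse(!recorded, "unrecorded",
                   ifelse(recognised, "purebred", "crossbred"))
  kc_group <- rep(NA_character_, length(key))
  kc_group[recognised] <- ifelse(key[recognised] %in% names(lookup$groups),
                                 unname(lookup$groups[key[recognised]]),
                                 "non-KC recognised")
  data.frame(purity = purity, kc_group = kc_group, stringsAsFactors = FALSE)
}

#' Add breed-derived stratum columns to a cohort
#'
#' @param cohort a cohort data frame from [apply_inclusion_filters()].
#' @param lookup a [read_breed_classifier()] result.
#' @return the cohort with `purity` and `kc_group` columns appended.
#' @export
add_breed_strata <- function(cohort, lookup = read_breed_classifier()) {
  cls <- classify_breed(cohort$breed, lookup)
  cohort$purity <- cls$purity
  cohort$kc_group <- cls$kc_group
  cohort
}

stratum_schemes <- c("overall", "sex", "sex_neuter", "kc_group", "breed")

#' Partition a cohort into strata
#'
#' Supported schemes: `overall`; `sex` (female/male); `sex_neuter`
#' (e.g. `female_entire`); `kc_group` (breed groups of purebred dogs,
#' including `"non-KC recognised"`); `breed` (each purebred breed, plus
#' `"Crossbred"`). Within each scheme the labels partition the animals that
#' carry that label; animals with unknown/unrecorded values are excluded
#' from that scheme only.
#'
#' @param cohort a cohort data frame; `kc_group`/`breed` schemes need the
#'   columns added by [add_breed_strata()].
#' @param schemes character vector of scheme names.
#' @return named list: scheme -> named list of label -> sub-cohort.
#' @export
stratify <- function(cohort, schemes = c("overall", "sex")) {
  bad <- setdiff(schemes, stratum_schemes)
  if (length(bad) > 0)
    stop_config(sprintf("unknown stratification scheme(s): %s (known: %s)",
                        paste(bad, collapse = ", "),
                        paste(stratum_schemes, collapse = ", ")))
  need_breed <- intersect(schemes, c("kc_group", "breed"))
  if (length(need_breed) > 0 && !"purity" %in% names(cohort))
    stop_config("kc_group/breed schemes need add_breed_strata() columns")
  out <- list()
  for (scheme in schemes) {
    lab <- switch(scheme,
      overall = rep("overall", nrow(cohort)),
      sex = ifelse(cohort$sex %in% c("female", "male"), cohort$sex, NA),
      sex_neuter = ifelse(cohort$sex %in% c("female", "male") &
                          cohort$neuter_status %in% c("neutered", "entire"),
                          paste(cohort$sex, cohort$neuter_status, sep = "_"), NA),
      kc_group = ifelse(cohort$purity == "purebred", cohort$kc_group, NA),
      breed = ifelse(cohort$purity == "purebred", cohort$breed,
                     ifelse(cohort$purity == "crossbred", "Crossbred", NA)))
    keep <- !is.na(lab)
    out[[scheme]] <- split(cohort[keep, , drop = FALSE], lab[keep])
  }
  out
}
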