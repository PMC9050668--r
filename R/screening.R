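#' Tokenize free text
#'
#' Case-folds and splits on any run of punctuation or whitespace; empty text
#' yields an empty token vector. Tokenizing the space-joined output of
#' `tokenize` is a fixed point.
#'
#' @param text a character scalar (or vector, tokenized elementwise into a list).
#' @return character vector of lowercase tokens (or list thereof).
#' @export
tokenize <- function(text) {
  one <- function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    toks <- strsplit(tolower(s), "[^a-z0-9]+")[[1]]
    toks[nzchar(toks)]
  }
  if (length(text) == 1) one(text) else lapply(text, one)
}

#' Parse a search term
#'
#' Grammar (mirroring common clinical-record search engines):
#' \itemize{
#'   \item bare word: matches a whole token, case-insensitively ("euth")
#'   \item trailing `*`: prefix match ("pts*" matches "pts" and "ptsd")
#'   \item quoted multiword: consecutive-token phrase ("\"put to sleep\"")
#'   \item quoted phrase with `~ k`: all phrase words within a window
#'     allowing up to k intervening tokens, in any order ("\"home bury\" ~ 1")
#'   \item bracketed conjunction: all listed words anywhere in the field
#'     ("[\"bury\" and \"home\"]")
#' }
#'
#' @param raw the term as written.
#' @return an object of class `search_term` with fields `raw`, `kind`,
#'   `tokens` and (proximity only) `k`.
#' @export
parse_search_term <- function(raw) {
  s <- trimws(raw)
  if (!nzchar(s)) stop_config("empty search term")
  mk <- function(kind, tokens, k = NA_integer_) {
    if (any(!nzchar(tokens))) stop_config(sprintf("malformed search term: %s", raw))
    structure(list(raw = raw, kind = kind, tokens = tolower(tokens), k = k),
              class = "search_term")
  }
  if (grepl("^\\[.*\\]$", s)) {
    inner <- substr(s, 2, nchar(s) - 1)
    parts <- strsplit(inner, "(?i)\\band\\b", perl = TRUE)[[1]]
    words <- trimws(gsub('"', "", parts))
    words <- words[nzchar(words)]
    if (length(words) < 2) stop_config(sprintf("conjunction needs >= 2 words: %s", raw))
    return(mk("conjunction", words))
  }
  prox <- regmatches(s, regexec('^"([^"]+)"\\s*~\\s*([0-9]+)$', s))[[1]]
  if (length(prox) == 3) {
    words <- tokenize(prox[2])
    if (length(words) < 2) stop_config(sprintf("proximity needs a multiword phrase: %s", raw))
    return(mk("proximity", words, k = as.integer(prox[3])))
  }
  if (grepl("~", s, fixed = TRUE))
    stop_config(sprintf("'~' requires a quoted phrase followed by a number: %s", raw))
  if (grepl('^".*"$', s)) {
    words <- tokenize(substr(s, 2, nchar(s) - 1))
    if (length(words) == 0) stop_config(sprintf("empty phrase: %s", raw))
    if (length(words) == 1) return(mk("token", words))
    return(mk("phrase", words))
  }
  if (grepl("\\*", s)) {
    if (!grepl("^[^*]+\\*$", s))
      stop_config(sprintf("wildcard only allowed as a single trailing '*': %s", raw))
    return(mk("prefix", sub("\\*$", "", s)))
  }
  if (grepl("\\s", s)) stop_config(sprintf("unquoted multiword term: %s", raw))
  mk("token", s)
}

#' Default screening term lists
#'
#' The shipped configuration used to flag candidate deaths: one list applied
#' to the clinical-note field and one to the treatment field.
#'
#' @param path optional YAML file with `screening$note_terms` and
#'   `screening$treatment_terms`; defaults to the packaged configuration.
#' @return list with character vectors `note_terms` and `treatment_terms`.
#' @export
default_search_terms <- function(path = system.file("extdata", "search_terms.yaml",
                                                    package = "canlife")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$screening$note_terms) || is.null(cfg$screening$treatment_terms))
    stop_config("term config must define screening$note_terms and screening$treatment_terms")
  list(note_terms = as.character(cfg$screening$note_terms),
       treatment_terms = as.character(cfg$screening$treatment_terms))
}

#' Compile search terms into a field-aware matcher
#'
#' @param note_terms character vector of terms applied to `clinical_note`.
#' @param treatment_terms character vector applied to `treatment_text`.
#' @param bare_mode how bare terms match: `"token"` (whole token, default) or
#'   `"substring"` (anywhere inside a token).
#' @return an object of class `screen_matcher`.
#' @export
compile_terms <- function(note_terms, treatment_terms,
                          bare_mode = c("token", "substring")) {
  bare_mode <- match.arg(bare_mode)
  structure(list(note = lapply(note_terms, parse_search_term),
                 treatment = lapply(treatment_terms, parse_search_term),
                 bare_mode = bare_mode),
            class = "screen_matcher")
}

# offsets (1-based token positions) at which `term` hits in `tokens`
match_term <- function(term, tokens, bare_mode = "token") {
  m <- length(tokens)
  if (m == 0) return(integer(0))
  switch(term$kind,
    token = if (bare_mode == "substring")
              which(grepl(term$tokens, tokens, fixed = TRUE))
            else which(tokens == term$tokens),
    prefix = which(startsWith(tokens, term$tokens)),
    phrase = {
      p <- term$tokens
      np <- length(p)
      if (np > m) integer(0) else {
        starts <- seq_len(m - np + 1L)
        keep <- vapply(starts, function(i) all(tokens[i:(i + np - 1L)] == p), logical(1))
        starts[keep]
      }
    },
    proximity = {
      p <- term$tokens
      np <- length(p)
      span <- np + term$k
      if (np > m) integer(0) else {
        starts <- seq_len(m - np + 1L)
        keep <- vapply(starts, function(i) {
          w <- tokens[i:min(m, i + span - 1L)]
          # unordered: every phrase word (with multiplicity) inside the window,
          # and the window must begin on a phrase word
          tokens[i] %in% p && all(table(p) <= table(factor(w, levels = unique(c(p, w))))[names(table(p))])
        }, logical(1))
        starts[keep]
      }
    },
    conjunction = {
      pos <- lapply(term$tokens, function(w) which(tokens == w))
      if (all(lengths(pos) > 0)) min(unlist(pos)) else integer(0)
    }
  )
}

#' Screen records for candidate deaths
#'
#' Applies the matcher's note terms to `clinical_note` and treatment terms to
#' `treatment_text`. Deterministic and order-independent: each record is
#' screened in isolation.
#'
#' @param records a `death_records` data frame.
#' @param matcher a [compile_terms()] matcher.
#' @return a data frame of class `screen_results` with columns `animal_id`,
#'   `matched`, and a list-column `hits` of data frames
#'   (`field`, `term`, `offset`) for audit.
#' @export
screen_records <- function(records, matcher) {
  stopifnot(inherits(matcher, "screen_matcher"))
  one <- function(note, treatment) {
    hits <- list()
    for (spec in list(list(field = "clinical_note", text = note, terms = matcher$note),
                      list(field = "treatment_text", text = treatment, terms = matcher$treatment))) {
      toks <- tokenize(spec$text)
      for (term in spec$terms) {
        off <- match_term(term, toks, matcher$bare_mode)
        if (length(off) > 0)
          hits[[length(hits) + 1L]] <- data.frame(field = spec$field,
                                                  term = term$raw,
                                                  offset = as.integer(off))
      }
    }
    if (length(hits) == 0)
      data.frame(field = character(0), term = character(0), offset = integer(0))
    else do.call(rbind, hits)
  }
  hits <- mapply(one, records$clinical_note, records$treatment_text,
                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
  out <- data.frame(animal_id = records$animal_id,
                    matched = vapply(hits, nrow, integer(1)) > 0)
  out$hits <- hits
  class(out) <- c("screen_results", "data.frame")
  out
}

#' Precision of the screening terms against confirmed labels
#'
#' @param results a `screen_results` data frame.
#' @param labels named logical vector, `animal_id -> confirmed death`; every
#'   matched id must be labelled.
#' @return list with `proportion` (confirmed among matched), `numerator`,
#'   `denominator`.
#' @export
screening_precision <- function(results, labels) {
  matched_ids <- results$animal_id[results$matched]
  unlabelled <- setdiff(matched_ids, names(labels))
  if (length(unlabelled) > 0)
    stop_data(sprintf("unlabelled matched id(s): %s",
                      paste(utils::head(unlabelled, 5), collapse = ", ")))
  den <- length(matched_ids)
  num <- sum(labels[matched_ids])
  list(proportion = if (den == 0) NA_real_ else num / den,
       numerator = as.integer(num), denominator = as.integer(den))
}
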