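# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (brute force, direct enumeration) so
# it stays independent of the implementation paths it checks.

# mean residual lifespan among survivors to age x, straight from definition
oracle_mean_residual <- function(lifespans, x) {
  alive <- lifespans[lifespans >= x]
  if (length(alive) == 0) return(NA_real_)
  mean(alive - x)
}

# brute-force final-interval choice: try every candidate start
oracle_final_interval <- function(counts, min_last) {
  ages <- as.integer(names(counts))
  cand <- Filter(function(x) sum(counts[ages >= x]) >= min_last, ages)
  if (length(cand) == 0) NA_integer_ else max(cand)
}

# ---- naive screening scanner ------------------------------------------------
# tokenises with the same published convention (lowercase, punctuation as
# separators) but matches terms by exhaustive enumeration of token windows.

naive_tokens <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

naive_term_hits <- function(raw, tokens) {
  s <- trimws(raw)
  m <- length(tokens)
  if (m == 0) return(FALSE)
  if (grepl("^\\[.*\\]$", s)) {
    words <- naive_tokens(gsub("\\band\\b", " ", substr(s, 2, nchar(s) - 1)))
    return(all(vapply(words, function(w) any(tokens == w), logical(1))))
  }
  prox <- regmatches(s, regexec('^"([^"]+)"\\s*~\\s*([0-9]+)$', s))[[1]]
  if (length(prox) == 3) {
    words <- naive_tokens(prox[2])
    k <- as.integer(prox[3])
    # enumerate every choice of |words| positions; accept if some assignment
    # matches the multiset with total span <= |words| + k
    if (length(words) > m) return(FALSE)
    combs <- utils::combn(m, length(words), simplify = FALSE)
    for (pos in combs) {
      if (max(pos) - min(pos) + 1L > length(words) + k) next
      if (identical(sort(tokens[pos]), sort(words))) return(TRUE)
    }
    return(FALSE)
  }
  if (grepl('^".*"$', s)) {
    words <- naive_tokens(substr(s, 2, nchar(s) - 1))
    if (length(words) > m) return(FALSE)
    for (i in 1:(m - length(words) + 1L))
      if (identical(tokens[i:(i + length(words) - 1L)], words)) return(TRUE)
    return(FALSE)
  }
  if (grepl("\\*$", s)) {
    stem <- tolower(sub("\\*$", "", s))
    return(any(substr(tokens, 1, nchar(stem)) == stem))
  }
  any(tokens == tolower(s))
}

naive_screen_one <- function(note, treatment, note_terms, treatment_terms) {
  nt <- naive_tokens(note)
  tt <- naive_tokens(treatment)
  any(vapply(note_terms, naive_term_hits, logical(1), tokens = nt)) ||
    any(vapply(treatment_terms, naive_term_hits, logical(1), tokens = tt))
}

# random clinical-style notes mixing death vocabulary with filler
random_note <- function(rng_words = c("euth", "pts", "ptsd", "cremation", "crematorium",
                                      "ashes", "pentobarbital", "casket", "beech",
                                      "deceased", "death", "put", "to", "sleep", "doa",
                                      "died", "killed", "home", "bury", "garden",
                                      "vaccine", "booster", "otitis", "the", "dog",
                                      "owner", "today", "at", "in"),
                        n_words = sample(0:12, 1)) {
  paste(sample(rng_words, n_words, replace = TRUE), collapse = " ")
}

# ---- record fixtures --------------------------------------------------------

make_records <- function(n = 5, ...) {
  defaults <- list(
    animal_id = sprintf("A%03d", seq_len(n)),
    breed = rep("Labrador Retriever", n),
    sex = rep("female", n),
    neuter_status = rep("neutered", n),
    birth_date = as.Date(rep("2008-05-01", n)),
    death_date = as.Date(rep("2017-06-15", n)),
    death_mechanism = rep("euthanased", n),
    clinical_note = rep("put to sleep today", n),
    treatment_text = rep("", n),
    insured = rep(FALSE, n))
  override <- list(...)
  for (nm in names(override)) defaults[[nm]] <- override[[nm]]
  out <- as.data.frame(defaults, stringsAsFactors = FALSE)
  class(out) <- c("death_records", "data.frame")
  out
}

write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  write_records(records, path)
  path
}

aggregates_fixture_path <- function() {
  system.file("extdata", "uk_dogs_lifetable_aggregates.csv", package = "canlife")
}

# seed under which every replicate of the 3-vs-11 borderline cohort in the
# estimation-error test is ineligible (3 iterations)
SEED_ALL_REJECTED <- 9L

# pseudo-cohort expansion of an aggregate table: d_x animals at x + a_hat_x
pseudo_cohort <- function(table) {
  r <- life_table_rows(table)
  rep(r$x + r$a_hat, r$d)
}
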