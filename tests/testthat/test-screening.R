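test_that("tokenize case-folds, splits on punctuation, and is idempotent", {
  expect_equal(tokenize("PTS today."), c("pts", "today"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize(NA_character_), character(0))
  expect_equal(tokenize("home-bury, (garden)!"), c("home", "bury", "garden"))
  set.seed(31)
  for (i in 1:25) {
    toks <- tokenize(random_note())
    expect_identical(tokenize(paste(toks, collapse = " ")), toks)
  }
})

test_that("the term grammar parses all five kinds and rejects malformed terms", {
  expect_equal(parse_search_term("euth")$kind, "token")
  expect_equal(parse_search_term("pts*")$kind, "prefix")
  expect_equal(parse_search_term('"put to sleep"')$tokens, c("put", "to", "sleep"))
  pr <- parse_search_term('"home bury" ~ 1')
  expect_equal(pr$kind, "proximity")
  expect_equal(pr$k, 1L)
  cj <- parse_search_term('["bury" and "home"]')
  expect_equal(cj$kind, "conjunction")
  expect_setequal(cj$tokens, c("bury", "home"))
  expect_error(parse_search_term("bury ~ 1"), class = "canlife_config_error")
  expect_error(parse_search_term("cr*em"), class = "canlife_config_error")
  expect_error(parse_search_term("put to sleep"), class = "canlife_config_error")
  expect_error(parse_search_term(""), class = "canlife_config_error")
})

test_that("the shipped default configuration has 15 note and 6 treatment terms", {
  terms <- default_search_terms()
  expect_length(terms$note_terms, 15)
  expect_length(terms$treatment_terms, 6)
  expect_no_error(compile_terms(terms$note_terms, terms$treatment_terms))
})

test_that("bare terms match whole tokens, prefixes match stems", {
  m <- compile_terms(c("euth", "pts*"), character(0))
  sc <- function(note) screen_records(make_records(1, clinical_note = note,
                                                   treatment_text = ""), m)$matched
  expect_true(sc("euth discussed"))
  expect_false(sc("euthanasia discussed"))   # bare term is not a prefix
  expect_true(sc("pts given"))
  expect_true(sc("ptsd noted"))              # trailing * is
  m2 <- compile_terms("euth", character(0), bare_mode = "substring")
  expect_true(screen_records(make_records(1, clinical_note = "euthanasia discussed",
                                          treatment_text = ""), m2)$matched)
})

test_that("phrases, conjunctions and proximity terms match per the grammar", {
  terms <- default_search_terms()
  m <- compile_terms(terms$note_terms, terms$treatment_terms)
  sc <- function(note) screen_records(make_records(1, clinical_note = note,
                                                   treatment_text = ""), m)
  r <- sc("dog was put to sleep at home")
  expect_true(r$matched)
  expect_true("\"put to sleep\"" %in% r$hits[[1]]$term)
  r2 <- sc("will bury her at home")
  expect_true(r2$matched)
  expect_true('["bury" and "home"]' %in% r2$hits[[1]]$term)
  prox <- compile_terms('"home bury" ~ 1', character(0))
  expect_true(screen_records(make_records(1, clinical_note = "home to bury",
                                          treatment_text = ""), prox)$matched)
  expect_true(screen_records(make_records(1, clinical_note = "bury at home",
                                          treatment_text = ""), prox)$matched)
  expect_false(screen_records(make_records(1, clinical_note = "home in the garden bury",
                                           treatment_text = ""), prox)$matched)
})

test_that("treatment terms apply to the treatment field only", {
  terms <- default_search_terms()
  m <- compile_terms(terms$note_terms, terms$treatment_terms)
  r <- screen_records(make_records(1, clinical_note = "routine check",
                                   treatment_text = "scatter tube"), m)
  expect_true(r$matched)
  expect_equal(unique(r$hits[[1]]$field), "treatment_text")
  r2 <- screen_records(make_records(1, clinical_note = "scatter mentioned",
                                    treatment_text = ""), m)
  expect_false(r2$matched)   # "scatter" is a treatment-field term
})

test_that("empty term lists match nothing and matched <=> hits non-empty", {
  m <- compile_terms(character(0), character(0))
  r <- screen_records(make_records(3), m)
  expect_false(any(r$matched))
  terms <- default_search_terms()
  m2 <- compile_terms(terms$note_terms, terms$treatment_terms)
  r2 <- screen_records(make_records(2, clinical_note = c("pts", "nothing here"),
                                    treatment_text = ""), m2)
  expect_equal(r2$matched, vapply(r2$hits, nrow, integer(1)) > 0)
})

test_that("the matcher agrees with a naive windowed scanner on random notes", {
  terms <- default_search_terms()
  m <- compile_terms(terms$note_terms, terms$treatment_terms)
  set.seed(97)
  notes <- replicate(120, random_note())
  treats <- replicate(120, random_note(n_words = sample(0:5, 1)))
  recs <- make_records(120, clinical_note = notes, treatment_text = treats)
  got <- screen_records(recs, m)$matched
  want <- mapply(naive_screen_one, notes, treats,
                 MoreArgs = list(note_terms = terms$note_terms,
                                 treatment_terms = terms$treatment_terms))
  expect_equal(got, unname(want))
})

test_that("screening is order-independent and idempotent over records", {
  terms <- default_search_terms()
  m <- compile_terms(terms$note_terms, terms$treatment_terms)
  set.seed(5)
  recs <- make_records(40, clinical_note = replicate(40, random_note()),
                       treatment_text = "")
  r1 <- screen_records(recs, m)
  r2 <- screen_records(recs, m)
  expect_identical(r1, r2)
  perm <- sample(nrow(recs))
  r3 <- screen_records(recs[perm, ], m)
  expect_equal(r3$matched[order(perm)], r1$matched)
})

test_that("screening precision is confirmed-among-matched with its counts", {
  res <- data.frame(animal_id = sprintf("A%05d", 1:32390),
                    matched = TRUE)
  res$hits <- replicate(nrow(res), data.frame(), simplify = FALSE)
  class(res) <- c("screen_results", "data.frame")
  labels <- setNames(c(rep(TRUE, 30635), rep(FALSE, 32390 - 30635)), res$animal_id)
  p <- screening_precision(res, labels)
  expect_equal(round(100 * p$proportion, 1), 94.6)
  expect_equal(p$numerator, 30635L)
  expect_equal(p$denominator, 32390L)

  small <- res[1:3, ]
  expect_equal(screening_precision(small, setNames(rep(TRUE, 3), small$animal_id))$proportion, 1)
  expect_equal(round(100 * screening_precision(
    small, setNames(c(TRUE, FALSE, FALSE), small$animal_id))$proportion, 1), 33.3)
  expect_error(screening_precision(small, c(A00001 = TRUE)),
               "unlabelled", class = "canlife_data_error")
})
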