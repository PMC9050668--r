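test_that("lifespans are day counts divided by 365.25", {
  expect_equal(compute_lifespan(as.Date("2016-03-01"), as.Date("2016-03-01")), 0)
  # independent calendar arithmetic: 2010-03-01 .. 2016-03-01 spans two leap days
  days <- as.numeric(as.Date("2016-03-01") - as.Date("2010-03-01"))
  expect_equal(days, 4 * 365 + 2 * 366)
  expect_equal(compute_lifespan(as.Date("2010-03-01"), as.Date("2016-03-01")),
               days / 365.25)
  expect_lt(compute_lifespan(as.Date("2016-03-01"), as.Date("2015-03-01")), 0)
  expect_true(is.na(compute_lifespan(as.Date(NA), as.Date("2016-03-01"))))
})

test_that("exclusions apply in the fixed order and reconcile with inclusions", {
  rec <- make_records(
    6,
    birth_date = as.Date(c("2008-05-01", "2008-05-01", NA, "2018-01-01",
                           "2008-05-01", "2008-05-01")),
    death_date = as.Date(c("2017-06-15", "2015-12-31", "2016-06-01",
                           "2017-01-01", NA, "2017-06-15")),
    sex = c("female", "unknown", "male", "male", "female", "unknown"))
  res <- apply_inclusion_filters(rec)
  expect_equal(res$exclusions$n_included, 1)   # only row 1 survives
  counts <- res$exclusions$counts
  expect_equal(unname(counts["outside_window"]), 1)        # row 2 (death 2015-12-31, despite unknown sex)
  expect_equal(unname(counts["negative_lifespan"]), 1)     # row 4
  expect_equal(unname(counts["missing_birth_or_death"]), 2) # rows 3 and 5
  expect_equal(unname(counts["missing_sex"]), 1)           # row 6
  expect_equal(sum(counts) + res$exclusions$n_included, nrow(rec))
  expect_equal(res$cohort$animal_id, c("A001"))
})

test_that("a death just before the window start is excluded as outside_window", {
  rec <- make_records(1, death_date = as.Date("2015-12-31"))
  res <- apply_inclusion_filters(rec)
  expect_equal(res$exclusions$reasons$reason, "outside_window")
  rec2 <- make_records(1, death_date = as.Date("2016-01-01"))
  expect_equal(apply_inclusion_filters(rec2)$exclusions$n_included, 1)
  rec3 <- make_records(1, death_date = as.Date("2020-08-01"))
  expect_equal(apply_inclusion_filters(rec3)$exclusions$reasons$reason, "outside_window")
})

test_that("filtering is permutation-invariant and idempotent", {
  set.seed(19)
  n <- 120
  rec <- make_records(
    n,
    birth_date = as.Date("2008-05-01") + sample(c(0:2000, NA), n, replace = TRUE),
    death_date = as.Date("2014-01-01") + sample(c(0:3000, NA), n, replace = TRUE),
    sex = sample(c("female", "male", "unknown"), n, replace = TRUE))
  res <- apply_inclusion_filters(rec)
  expect_equal(sum(res$exclusions$counts) + nrow(res$cohort), n)
  perm <- sample(n)
  res2 <- apply_inclusion_filters(rec[perm, ])
  expect_equal(res2$exclusions$counts, res$exclusions$counts)
  expect_equal(sort(res2$cohort$animal_id), sort(res$cohort$animal_id))
  # idempotence: re-filtering the survivors changes nothing
  surv <- rec[rec$animal_id %in% res$cohort$animal_id, ]
  res3 <- apply_inclusion_filters(surv)
  expect_equal(res3$cohort$lifespan_years, res$cohort$lifespan_years)
  expect_equal(sum(res3$exclusions$counts), 0)
})

test_that("breed classification follows the two-level recognised/group rule", {
  lookup <- read_breed_classifier()
  cls <- classify_breed(c("Labrador Retriever", "", "American Bulldog",
                          "Lurcher Cross", "  labrador retriever  "), lookup)
  expect_equal(cls$purity, c("purebred", "unrecorded", "purebred",
                             "crossbred", "purebred"))
  expect_equal(cls$kc_group, c("Gundog", NA, "non-KC recognised", NA, "Gundog"))
})

test_that("stratification partitions labelled animals within each scheme", {
  cohort <- data.frame(
    animal_id = sprintf("A%02d", 1:5),
    lifespan_years = c(10, 11, 12, 13, 14),
    sex = c("female", "female", "male", "male", "male"),
    neuter_status = c("entire", "neutered", "neutered", "neutered", "unknown"),
    breed = c("Labrador Retriever", "Labrador Retriever", "Pug", "Collie Cross", ""))
  s <- stratify(cohort, c("overall", "sex", "sex_neuter"))
  expect_equal(vapply(s$sex, nrow, integer(1)), c(female = 2L, male = 3L))
  expect_equal(nrow(s$sex_neuter$female_entire), 1)
  expect_false("male_unknown" %in% names(s$sex_neuter))
  expect_equal(nrow(s$overall$overall), 5)
  # partition: within a scheme the labels are disjoint and cover the labelled
  ids <- unname(unlist(lapply(s$sex, `[[`, "animal_id")))
  expect_equal(sort(ids), sort(cohort$animal_id[cohort$sex != "unknown"]))
  expect_equal(anyDuplicated(ids), 0)

  cohort2 <- add_breed_strata(cohort)
  s2 <- stratify(cohort2, c("kc_group", "breed"))
  expect_equal(sort(names(s2$breed)), sort(c("Labrador Retriever", "Pug", "Crossbred")))
  expect_equal(nrow(s2$kc_group$Gundog), 2)
  expect_error(stratify(cohort, "postcode"), "unknown stratification",
               class = "canlife_config_error")
})

test_that("demographic proportions come out at one decimal place", {
  cohort <- data.frame(sex = rep(c("female", "male"), c(14574, 30563 - 14574)))
  dem <- demography_summary(cohort)
  expect_equal(dem$pct[dem$level == "female"], 47.7)
  expect_equal(sum(dem$n), 30563)
})
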