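#' Parametric age-specific mortality schedule
#'
#' Drives the registry simulator. Three forms:
#' \itemize{
#'   \item `constant`: hazard `lambda` per year (exponential lifespans);
#'   \item `gompertz_makeham`: hazard `lambda + a exp(b t)` — an
#'     age-independent background rate plus exponentially rising senescent
#'     mortality, the standard shape for populations whose interval death
#'     probability rises with age;
#'   \item `piecewise_interval`: per-year interval death probabilities `q`
#'     (the last entry must be 1), with deaths uniform within the interval.
#' }
#' The defaults (`lambda` = 0.01, `a` = 5e-4, `b` = 0.55) give a
#' life expectancy at age 0 of roughly 11-12 years with a plausibly shaped
#' rising mortality profile; this is a demonstration configuration, not a
#' fit to any population.
#'
#' @param form one of `"constant"`, `"gompertz_makeham"`, `"piecewise_interval"`.
#' @param lambda baseline hazard per year.
#' @param a,b Gompertz slope parameters (per year).
#' @param q per-interval death probabilities (piecewise form only).
#' @param label stratum name carried through to simulated records.
#' @return an object of class `hazard_schedule`.
#' @export
hazard_schedule <- function(form = c("gompertz_makeham", "constant", "piecewise_interval"),
                            lambda = 0.01, a = 5e-4, b = 0.55, q = NULL,
                            label = "demo") {
  form <- match.arg(form)
  if (form == "piecewise_interval") {
    if (is.null(q) || length(q) == 0) stop_config("piecewise form needs q")
    if (any(q < 0 | q > 1)) stop_config("piecewise q values must lie in [0, 1]")
    if (q[length(q)] != 1)
      stop_config("the last piecewise q must be 1 (everyone eventually dies)")
  } else {
    if (lambda < 0 || a < 0) stop_config("hazard parameters must be non-negative")
    if (form == "constant" && lambda == 0) stop_config("degenerate hazard: all zero")
    if (form == "gompertz_makeham" && lambda == 0 && a == 0)
      stop_config("degenerate hazard: all zero")
  }
  structure(list(form = form, lambda = lambda, a = a, b = b, q = q, label = label),
            class = "hazard_schedule")
}

# cumulative hazard H(t) and survival S(t) = exp(-H(t))
cumulative_hazard <- function(schedule, t) {
  switch(schedule$form,
         constant = schedule$lambda * t,
         gompertz_makeham = schedule$lambda * t +
           (schedule$a / schedule$b) * (exp(schedule$b * t) - 1),
         stop_config("cumulative hazard undefined for piecewise form"))
}

survival_at <- function(schedule, t) {
  if (schedule$form == "piecewise_interval") {
    # survival at integer boundaries; linear interpolation within intervals
    q <- schedule$q
    Sb <- cumprod(c(1, 1 - q))
    ti <- floor(t)
    ti2 <- pmin(ti, length(q) - 1)
    frac <- t - ti
    ifelse(ti >= length(q), 0,
           Sb[ti2 + 1] * (1 - frac * q[ti2 + 1]))
  } else {
    exp(-cumulative_hazard(schedule, t))
  }
}

#' Sample lifespans from a hazard schedule
#'
#' Inverse-CDF sampling: an Exp(1) draw E is mapped to the t solving
#' H(t) = E (closed form for the constant hazard; vectorised Newton
#' iteration on the convex cumulative hazard for Gompertz-Makeham). The
#' piecewise form draws the death interval from its per-year probabilities
#' and a uniform position within it. Values are continuous so the mean
#' fraction of the last year lived is estimable.
#'
#' @param schedule a [hazard_schedule()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of lifespans in years.
#' @export
sample_lifespans <- function(schedule, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  switch(schedule$form,
    constant = stats::rexp(n, rate = schedule$lambda),
    gompertz_makeham = {
      E <- stats::rexp(n)
      lam <- schedule$lambda; a <- schedule$a; b <- schedule$b
      # Newton on H(t) - E = 0; H convex so iterates starting above the
      # root converge monotonically. Start from a generous upper bound.
      up <- if (a > 0) log1p(E * b / a) / b else 0
      t <- pmax(if (lam > 0) E / lam else Inf, 0)
      t <- pmin(t, up + 1)
      for (i in 1:100) {
        H <- lam * t + (a / b) * (exp(b * t) - 1)
        h <- lam + a * exp(b * t)
        step <- (H - E) / h
        t <- pmax(t - step, 0)
        if (max(abs(step)) < 1e-12) break
      }
      t
    },
    piecewise_interval = {
      q <- schedule$q
      k <- length(q)
      Sb <- cumprod(c(1, 1 - q))           # survival at 0..k
      p_int <- Sb[1:k] * q                 # P(die in interval i-1)
      idx <- sample.int(k, n, replace = TRUE, prob = p_int) - 1L
      idx + stats::runif(n)
    })
}

#' Analytic remaining life expectancy under a hazard schedule
#'
#' The expected further lifetime of an individual alive at `age`:
#' the integral of the conditional survival function. Closed form for the
#' constant hazard (memoryless: always 1/lambda); adaptive quadrature for
#' Gompertz-Makeham (absolute tolerance 1e-8); exact finite sum for the
#' piecewise form at integer ages.
#'
#' @param schedule a [hazard_schedule()].
#' @param age age in years (integer required for the piecewise form).
#' @return remaining life expectancy in years.
#' @export
true_life_expectancy <- function(schedule, age = 0) {
  switch(schedule$form,
    constant = 1 / schedule$lambda,
    gompertz_makeham = {
      lam <- schedule$lambda; a <- schedule$a; b <- schedule$b
      f <- function(u) exp(-(lam * u + (a / b) * exp(b * age) * (exp(b * u) - 1)))
      stats::integrate(f, 0, Inf, abs.tol = 1e-10, rel.tol = 1e-10)$value
    },
    piecewise_interval = {
      if (age != floor(age)) stop_config("piecewise expectancy needs an integer age")
      q <- schedule$q
      k <- length(q)
      if (age >= k) stop_config("age beyond the schedule's support")
      Sb <- cumprod(c(1, 1 - q))
      S_age <- Sb[age + 1]
      j <- age:(k - 1)
      # death in interval j contributes (j - age + 1/2) on average
      sum(Sb[j + 1] * q[j + 1] * (j - age + 0.5)) / S_age
    })
}

#' Configuration for the synthetic registry
#'
#' Describes the population the simulator emulates: per-stratum hazard
#' schedules; sex and neuter mix; a birth-year process whose weights can
#' grow exponentially (`growth` > 0 emulates a breed soaring in popularity,
#' which skews a deceased-only cohort towards young deaths); the death
#' observation window; missingness rates; and how often the clinical note
#' records the death in screenable language.
#'
#' @param n number of animals drawn (before window truncation).
#' @param strata data frame with columns `breed` and `weight` (sampling
#'   weights); defaults to a small mixed population.
#' @param schedules named list breed -> [hazard_schedule()]; breeds not
#'   listed use the `"default"` entry.
#' @param p_female,p_neutered marginal probabilities of the sex/neuter mix.
#' @param birth_years integer vector of candidate birth years.
#' @param growth exponential growth rate of birth-cohort size per year.
#' @param window an [inclusion_window()]: only deaths inside it are emitted.
#' @param missing_sex,missing_birth,missing_death missingness rates in [0, 1].
#' @param note_positive_rate probability the clinical note carries a
#'   death-related phrase the screening terms can find.
#' @param p_insured probability the insurance flag is set.
#' @return an object of class `registry_config`.
#' @export
registry_config <- function(n = 5000L,
                            strata = data.frame(
                              breed = c("Labrador Retriever", "Jack Russell Terrier",
                                        "French Bulldog", ""),
                              weight = c(0.35, 0.3, 0.1, 0.25)),
                            schedules = list(default = hazard_schedule()),
                            p_female = 0.477, p_neutered = 0.574,
                            birth_years = 1990:2020, growth = 0,
                            window = inclusion_window(),
                            missing_sex = 0, missing_birth = 0, missing_death = 0,
                            note_positive_rate = 0.95,
                            p_insured = 0.17) {
  rates <- c(missing_sex, missing_birth, missing_death, note_positive_rate, p_insured,
             p_female, p_neutered)
  if (any(rates < 0 | rates > 1)) stop_config("all rates must lie in [0, 1]")
  if (!inherits(window, "inclusion_window")) stop_config("window must be an inclusion_window")
  if (is.null(schedules$default) && !all(strata$breed %in% names(schedules)))
    stop_config("schedules must cover every breed or provide a 'default'")
  structure(list(n = as.integer(n), strata = strata, schedules = schedules,
                 p_female = p_female, p_neutered = p_neutered,
                 birth_years = as.integer(birth_years), growth = growth,
                 window = window,
                 missing_sex = missing_sex, missing_birth = missing_birth,
                 missing_death = missing_death,
                 note_positive_rate = note_positive_rate,
                 p_insured = p_insured),
            class = "registry_config")
}

death_note_phrases <- c(
  "owner elected euth after long discussion",
  "pts at the clinic this morning",
  "cremation arranged, ashes to be returned to owner",
  "put to sleep peacefully with owner present",
  "owner will bury her at home in the garden",
  "home bury arranged by the family",
  "sadly died overnight in kennels",
  "found deceased at home this morning",
  "casket collected by the family",
  "pentobarbital given, death confirmed")
neutral_note_phrases <- c(
  "annual booster vaccination given",
  "mild otitis externa, ear drops dispensed",
  "routine post operative check, healing well",
  "weight clinic visit, diet discussed")
death_treatment_phrases <- c(
  "euthatal injection", "pentobarbital solution", "cremation individual",
  "casket standard", "scatter tube", "")

#' Simulate an individual-level death registry
#'
#' Draws animals per [registry_config()]: breed stratum, sex, neuter status,
#' a birth date from the (possibly growing) birth-year process, a lifespan
#' from the stratum's hazard schedule, and a death date; only animals whose
#' death falls inside the observation window are emitted, mirroring a
#' deceased-only cohort (no censoring records). Requested fractions of
#' records lose sex or a date, and clinical notes carry death phrases drawn
#' from the screening term families so screening has true positives.
#'
#' @param config a [registry_config()].
#' @param seed integer seed; fixed seed gives a byte-identical registry.
#' @return a `death_records` data frame.
#' @export
simulate_registry <- function(config, seed = NULL) {
  stopifnot(inherits(config, "registry_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  breeds <- as.character(config$strata$breed)
  stratum <- sample.int(length(breeds), n, replace = TRUE,
                        prob = config$strata$weight)
  breed <- breeds[stratum]
  sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  neuter <- ifelse(stats::runif(n) < config$p_neutered, "neutered", "entire")
  yrs <- config$birth_years
  wts <- exp(config$growth * (yrs - min(yrs)))
  birth_year <- sample(yrs, n, replace = TRUE, prob = wts)
  year_start <- as.Date(sprintf("%d-01-01", birth_year))
  year_len <- as.numeric(as.Date(sprintf("%d-01-01", birth_year + 1L)) - year_start)
  birth <- year_start + floor(stats::runif(n) * year_len)
  lifespan <- numeric(n)
  for (b in unique(breed)) {
    sched <- config$schedules[[b]] %||% config$schedules$default
    idx <- which(breed == b)
    lifespan[idx] <- sample_lifespans(sched, length(idx))
  }
  death <- birth + round(lifespan * 365.25)
  emit <- death >= config$window$start & death <= config$window$end
  m <- sum(emit)
  if (m == 0) {
    warning("no simulated deaths fell inside the observation window")
  }
  idx <- which(emit)
  note_pos <- stats::runif(m) < config$note_positive_rate
  note <- ifelse(note_pos,
                 sample(death_note_phrases, m, replace = TRUE),
                 sample(neutral_note_phrases, m, replace = TRUE))
  treatment <- ifelse(note_pos & stats::runif(m) < 0.6,
                      sample(death_treatment_phrases, m, replace = TRUE), "")
  mech <- sample(c("euthanased", "unassisted", "unrecorded"), m,
                 replace = TRUE, prob = c(0.7, 0.2, 0.1))
  out <- data.frame(
    animal_id = sprintf("SYN%06d", seq_len(m)),
    breed = breed[idx],
    sex = ifelse(stats::runif(m) < config$missing_sex, "unknown", sex[idx]),
    neuter_status = neuter[idx],
    birth_date = as.Date(ifelse(stats::runif(m) < config$missing_birth,
                                NA, birth[idx]), origin = "1970-01-01"),
    death_date = as.Date(ifelse(stats::runif(m) < config$missing_death,
                                NA, death[idx]), origin = "1970-01-01"),
    death_mechanism = mech,
    clinical_note = note,
    treatment_text = treatment,
    insured = stats::runif(m) < config$p_insured,
    stringsAsFactors = FALSE)
  class(out) <- c("death_records", "data.frame")
  out
}
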