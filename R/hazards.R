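#' Parametric age-specific hazard for one cause of death
#'
#' Closed-form hazard curves used by the synthetic-data generator, chosen to
#' reproduce the qualitative age patterns seen in opioid-using cohorts:
#'
#' * `"constant"`: rate `level` at every age (`params = c(level)`).
#' * `"loglinear"`: Gompertz-type, `log rate = log(level18) + slope * (age - 18)`
#'   (`params = c(level18, slope)`); the monotone rise of smoking-related,
#'   other-cancer and cardiovascular mortality.
#' * `"unimodal"`: log-quadratic, `log rate = log(peak_rate) - curv * (age - peak)^2`
#'   with `curv > 0` and an interior peak (`params = c(peak_rate, peak, curv)`);
#'   drug-poisoning mortality rising to the late 40s then declining.
#' * `"plateau"`: logistic in the rate, `rate = plateau * plogis(k * (age - mid))`
#'   with `k > 0` (`params = c(plateau, mid, k)`); viral-hepatitis mortality
#'   rising then flattening near age 58.
#'
#' All rates are deaths per person-year and are strictly positive and finite
#' on ages 18-69.
#'
#' @param cause cause-category label.
#' @param shape one of `"constant"`, `"loglinear"`, `"unimodal"`, `"plateau"`.
#' @param params numeric coefficients of the chosen form (see above).
#' @return An object of class `hazard_spec`.
#' @export
hazard_spec <- function(cause, shape = c("constant", "loglinear",
                                         "unimodal", "plateau"),
                        params) {
  shape <- match.arg(shape)
  params <- as.numeric(params)
  npar <- c(constant = 1L, loglinear = 2L, unimodal = 3L, plateau = 3L)[shape]
  if (length(params) != npar) {
    stop(sprintf("shape '%s' needs %d parameters, got %d",
                 shape, npar, length(params)))
  }
  if (params[1] <= 0 || !is.finite(params[1])) {
    stop("level parameter must be positive and finite")
  }
  if (shape == "unimodal") {
    if (params[3] <= 0) stop("unimodal curvature must be positive")
    if (params[2] <= AGE_START || params[2] >= AGE_END) {
      stop("unimodal peak must lie strictly inside the age range")
    }
  }
  if (shape == "plateau" && params[3] <= 0) {
    stop("plateau steepness must be positive")
  }
  structure(list(cause = as.character(cause), shape = shape, params = params),
            class = "hazard_spec")
}

#' @export
print.hazard_spec <- function(x, ...) {
  cat(sprintf("hazard_spec '%s' (%s): %s\n", x$cause, x$shape,
              paste(signif(x$params, 4), collapse = ", ")))
  invisible(x)
}

#' Evaluate the true hazard of a spec at given ages
#'
#' Deterministic oracle for parameter-recovery tests: the exact rate implied
#' by a [hazard_spec()] at integer ages.
#'
#' @param spec a `hazard_spec`.
#' @param age integer age(s) in `[18, 69]`.
#' @return Deaths per person-year, same length as `age`.
#' @export
true_rate <- function(spec, age) {
  stopifnot(inherits(spec, "hazard_spec"))
  if (any(age < AGE_START | age > AGE_END)) {
    stop(sprintf("age outside modelled range [%d, %d]", AGE_START, AGE_END))
  }
  p <- spec$params
  switch(spec$shape,
         constant = rep(p[1], length(age)),
         loglinear = p[1] * exp(p[2] * (age - AGE_START)),
         unimodal = p[1] * exp(-p[3] * (age - p[2])^2),
         plateau = p[1] * stats::plogis(p[3] * (age - p[2])))
}

#' Person-years of observation per single year of age
#'
#' @param person_years non-negative numeric vector, one entry per modelled
#'   age (18-69); at least one must be positive.
#' @return Named numeric vector of class `exposure_schedule`.
#' @export
exposure_schedule <- function(person_years) {
  ages <- model_ages()
  person_years <- as.numeric(person_years)
  if (length(person_years) != length(ages)) {
    stop(sprintf("schedule must have %d entries (ages %d-%d)",
                 length(ages), AGE_START, AGE_END))
  }
  if (any(!is.finite(person_years)) || any(person_years < 0)) {
    stop("person-years must be finite and non-negative")
  }
  if (!any(person_years > 0)) stop("at least one age needs positive person-years")
  structure(stats::setNames(person_years, ages), class = "exposure_schedule")
}

#' Default observation-time profile
#'
#' A right-skewed person-years schedule emulating a cohort recruited mostly
#' in its 30s and 40s: entry age lognormal (median 35.1, IQR roughly
#' 29-42.3) convolved with a gamma(shape 2) follow-up whose median is 8.7
#' years, then truncated at age 70. Only the shape matters for rate
#' estimation; `total` sets the overall person-years.
#'
#' @param total total person-years across ages 18-69 (default 1e6, about
#'   what a cohort of 1e5 people observed for a decade contributes).
#' @return An [exposure_schedule()].
#' @export
default_schedule <- function(total = 1e6) {
  ages <- model_ages()
  entry <- stats::dlnorm(ages, meanlog = log(35.1), sdlog = 0.28)
  entry <- entry / sum(entry)
  # fraction of entrants at age e still under observation during [a, a+1)
  fup_surv <- function(t) stats::pgamma(t, shape = 2, scale = 8.7 / 1.67835,
                                        lower.tail = FALSE)
  w <- numeric(length(ages))
  for (i in seq_along(ages)) {
    e <- ages[seq_len(i)]
    w[i] <- sum(entry[seq_len(i)] * fup_surv(ages[i] - e + 0.5))
  }
  exposure_schedule(total * w / sum(w))
}

#' Hazard specs for the default synthetic cohort
#'
#' Six [hazard_spec()]s qualitatively matching the mortality of a cohort of
#' people who use illegal opioids: drug poisoning peaks at age 47, viral
#' hepatitis rises then plateaus near 58, and the three disease groups rise
#' monotonically. Each curve's level is calibrated so that, under
#' [default_schedule()], the expected number of deaths per cause equals the
#' cause totals of the emulated cohort (13 010 premature deaths in 1e6
#' person-years). Illustrative, not fitted to any real data.
#'
#' @param schedule schedule used for the level calibration
#'   (default [default_schedule()]).
#' @param target_deaths named vector of expected deaths per cause.
#' @return Named list of `hazard_spec`, one per cause in [default_causes()].
#' @export
default_hazards <- function(schedule = default_schedule(),
                            target_deaths = reference_cause_totals()) {
  ages <- model_ages()
  # unit-level shapes; levels rescaled below to hit the target totals
  shapes <- list(
    smoking_specific = hazard_spec("smoking_specific", "loglinear", c(1, 0.085)),
    other_cancers    = hazard_spec("other_cancers", "loglinear", c(1, 0.080)),
    cardiovascular   = hazard_spec("cardiovascular", "loglinear", c(1, 0.075)),
    drug_poisoning   = hazard_spec("drug_poisoning", "unimodal", c(1, 47, 0.0015)),
    viral_hepatitis  = hazard_spec("viral_hepatitis", "plateau", c(1, 48, 0.25)),
    other            = hazard_spec("other", "loglinear", c(1, 0.020))
  )
  shapes <- shapes[default_causes()]
  lapply(shapes, function(s) {
    expected <- sum(true_rate(s, ages) * schedule)
    s$params[1] <- s$params[1] * target_deaths[[s$cause]] / expected
    s
  })
}

#' Expected premature deaths per cause in the emulated cohort
#'
#' The cause-of-death totals the default synthetic world is calibrated to
#' (13 010 deaths before age 70 in total).
#'
#' @return Named numeric vector over [default_causes()].
#' @export
reference_cause_totals <- function() {
  c(smoking_specific = 1179, other_cancers = 1168, cardiovascular = 1101,
    drug_poisoning = 4373, viral_hepatitis = 303, other = 4886)
}

#' Draw a synthetic counts table from hazard specs
#'
#' Death counts for each (age, cause) are independent Poisson draws with
#' mean `true_rate(spec, age) * person_years[age]`; the all-cause count per
#' age is their sum by construction. Reproducible given `seed`; the seed
#' drives a single local random stream and the caller's RNG state is left
#' untouched.
#'
#' @param specs list of [hazard_spec()], one per cause (unique labels).
#' @param schedule an [exposure_schedule()].
#' @param seed integer seed.
#' @return An [age_cause_table()].
#' @export
generate_counts <- function(specs = default_hazards(),
                            schedule = default_schedule(), seed) {
  stopifnot(is.list(specs), inherits(schedule, "exposure_schedule"))
  labels <- unname(vapply(specs, function(s) s$cause, character(1)))
  if (anyDuplicated(labels)) stop("duplicate cause labels in specs")
  ages <- model_ages()
  means <- vapply(specs, function(s) true_rate(s, ages) * as.numeric(schedule),
                  numeric(length(ages)))
  counts <- with_local_seed(seed, {
    matrix(stats::rpois(length(means), means), nrow = length(ages))
  })
  age_cause_table(data.frame(
    age = rep(ages, times = length(labels)),
    cause = rep(labels, each = length(ages)),
    deaths = as.vector(counts),
    person_years = rep(as.numeric(schedule), times = length(labels))
  ), causes = labels)
}

# run code under a temporary RNG seed, restoring the caller's state
with_local_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
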