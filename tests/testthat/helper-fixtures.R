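# shared fixtures: all tables are built in code, nothing is read from disk

# several acceptance criteria are documented as expected-to-fail on the
# synthetic stand-in; never let the progress reporter stop the run early
options(testthat.progress.max_fails = Inf)

ages <- lifedecomp::model_ages()

# table whose empirical rate is exactly `rate` at every age, split evenly
# across `causes` (deaths are exact, not sampled)
flat_table <- function(rate = 0.02, py = 1e5, causes = c("a", "b")) {
  per_cause <- rate * py / length(causes)
  stopifnot(per_cause == round(per_cause))
  age_cause_table(data.frame(
    age = rep(ages, times = length(causes)),
    cause = rep(causes, each = length(ages)),
    deaths = per_cause,
    person_years = py
  ), causes = causes)
}

# hazard matrix with one constant column per cause
flat_hazards <- function(rates) {
  h <- matrix(rep(rates, each = length(ages)), nrow = length(ages),
              dimnames = list(ages, names(rates)))
  h
}

# hand-built life_table object with prescribed total deaths per age
# (for testing the YLL operations against hand sums)
manual_life_table <- function(deaths_total, radix,
                              causes = "x", deaths_by_cause = NULL) {
  stopifnot(length(deaths_total) == length(ages))
  if (is.null(deaths_by_cause)) {
    deaths_by_cause <- matrix(deaths_total, ncol = 1,
                              dimnames = list(ages, causes))
  }
  survivors <- radix - cumsum(c(0, deaths_total[-length(deaths_total)]))
  structure(list(radix = radix, ages = ages, survivors = survivors,
                 deaths_total = deaths_total,
                 deaths_by_cause = deaths_by_cause,
                 cumulative_risk = cumsum(deaths_total) / radix,
                 causes = causes, conversion = "exponential"),
            class = "life_table")
}

# default synthetic world, computed once per test run
default_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      specs <- default_hazards()
      sch <- default_schedule()
      cache <<- list(
        specs = specs, schedule = sch,
        true_hazards = {
          h <- vapply(specs, function(s) true_rate(s, ages),
                      numeric(length(ages)))
          rownames(h) <- ages
          h
        },
        table = reference_counts()
      )
    }
    cache
  }
})
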