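#' Deterministic synthetic reference cohort
#'
#' A noise-free counts table for the default synthetic world: the death
#' count at each (age, cause) is the expected count
#' `true_rate * person_years`, apportioned to integers by the
#' largest-remainder rule so that each cause's total equals
#' [reference_cause_totals()] exactly (13 010 premature deaths, of which
#' 4373 drug poisoning).
#'
#' This table is a synthetic stand-in for the real cohort's deposited
#' aggregate counts, which cannot be redistributed here. It is built only
#' from published aggregate characteristics of that cohort (cause totals,
#' cohort size and observation-time profile, qualitative hazard shapes);
#' the headline life-table results were never used in its construction, so
#' outputs computed from it are illustrative of the method rather than
#' reproductions of the original estimates.
#'
#' @param schedule an [exposure_schedule()] (default [default_schedule()]).
#' @return An [age_cause_table()].
#' @export
reference_counts <- function(schedule = default_schedule()) {
  specs <- default_hazards(schedule)
  ages <- model_ages()
  totals <- reference_cause_totals()
  counts <- vapply(specs, function(s) {
    expected <- true_rate(s, ages) * as.numeric(schedule)
    round_preserving_total(expected, totals[[s$cause]])
  }, numeric(length(ages)))
  age_cause_table(data.frame(
    age = rep(ages, times = ncol(counts)),
    cause = rep(colnames(counts), each = length(ages)),
    deaths = as.vector(counts),
    person_years = rep(as.numeric(schedule), times = ncol(counts))
  ), causes = names(specs))
}

# integerize x (non-negative) so the result sums to `total`
# (largest-remainder / Hamilton apportionment; deterministic, ties by index)
round_preserving_total <- function(x, total) {
  stopifnot(all(x >= 0), total >= 0, total == round(total))
  scaled <- x * total / sum(x)
  base <- floor(scaled)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    frac <- scaled - base
    top <- order(frac, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  base
}
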