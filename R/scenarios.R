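#' Counterfactual elimination scenario
#'
#' Names a scenario and the set of exposures eliminated in it. An empty set
#' is the baseline (observed mortality rates).
#'
#' @param label scenario label.
#' @param eliminated character vector of exposure labels (possibly empty).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, eliminated = character()) {
  structure(list(label = as.character(label),
                 eliminated = as.character(eliminated)),
            class = "scenario_spec")
}

#' The standard scenario set
#'
#' Baseline plus elimination of illegal drugs, of tobacco smoking, and of
#' both, matching the shipped [default_attribution()] exposures.
#'
#' @return Named list of [scenario_spec()]s.
#' @export
default_scenarios <- function() {
  list(
    baseline = scenario_spec("baseline"),
    eliminate_drugs = scenario_spec("eliminate_drugs", "illegal_drugs"),
    eliminate_tobacco = scenario_spec("eliminate_tobacco", "tobacco"),
    eliminate_both = scenario_spec("eliminate_both",
                                   c("illegal_drugs", "tobacco"))
  )
}

#' Remove exposure-attributable hazard from a cause-specific hazard set
#'
#' Scales each cause's hazard by `1 - sum of the eliminated exposures'
#' attributable fractions`: `h'(a, c) = h(a, c) * (1 - sum_e AF(e, c))`.
#' With the shipped map, eliminating illegal drugs zeroes the
#' drug-poisoning and viral-hepatitis hazards; eliminating tobacco halves
#' the cardiovascular hazard and scales other cancers by 0.7. The
#' counterfactual all-cause hazard is the row sum of the result, so
#' competing risks are handled by rebuilding the life table.
#'
#' @param hazards age-by-cause hazard matrix (see [apportion_hazards()]).
#' @param amap an [attribution_map()].
#' @param spec a [scenario_spec()]; its exposures must exist in `amap`.
#' @return Hazard matrix of the same shape.
#' @export
apply_elimination <- function(hazards, amap, spec) {
  stopifnot(is.matrix(hazards), inherits(amap, "attribution_map"),
            inherits(spec, "scenario_spec"))
  unknown <- setdiff(spec$eliminated, exposures_of(amap))
  if (length(unknown)) {
    stop("scenario eliminates undeclared exposures: ",
         paste(unknown, collapse = ", "))
  }
  if (!length(spec$eliminated)) return(hazards)
  AF <- af_matrix(amap, colnames(hazards))
  removed <- colSums(AF[spec$eliminated, , drop = FALSE])
  if (any(removed > 1 + 1e-12)) {
    stop("eliminated fractions exceed 1 for: ",
         paste(colnames(hazards)[removed > 1 + 1e-12], collapse = ", "))
  }
  sweep(hazards, 2, pmin(pmax(1 - removed, 0), 1), `*`)
}

#' Run one scenario end to end
#'
#' Fit the rate models, apportion the all-cause hazard across causes,
#' remove the eliminated exposures' attributable hazard, rebuild the life
#' table, and decompose the remaining burden. Deterministic given inputs.
#'
#' @param table an [age_cause_table()].
#' @param spline a [spline_spec()].
#' @param amap an [attribution_map()].
#' @param spec a [scenario_spec()].
#' @param radix life-table radix, default 100 000.
#' @param causes declared cause set, default [default_causes()].
#' @return A `burden_summary` labelled with the scenario.
#' @export
run_scenario <- function(table, spline = spline_spec(),
                         amap = default_attribution(),
                         spec = scenario_spec("baseline"),
                         radix = 1e5, causes = default_causes()) {
  curves <- fit_all(table, spline, causes = causes)
  hazards <- apportion_hazards(curves)
  scenario_burden(hazards, amap, spec, radix = radix)
}

# scenario evaluation from prebuilt apportioned hazards (fast path reused
# by the Monte-Carlo loop, which refits the rates once per simulation)
scenario_burden <- function(hazards, amap, spec, radix = 1e5) {
  h <- apply_elimination(hazards, amap, spec)
  lt <- build_life_table(cause_curves = h, radix = radix)
  attribute_burden(lt, counterfactual_attribution(amap, spec),
                   scenario_label = spec$label)
}

#' Attribution map for the deaths that remain after elimination
#'
#' Removing exposure `e` strips the fraction `AF(e, c)` out of each cause's
#' hazard, so none of the remaining deaths from that cause are attributable
#' to `e` any more: its fractions drop to 0. A non-eliminated exposure
#' keeps its absolute attributable hazard, which as a fraction of the
#' *remaining* hazard is `AF(e2, c) / (1 - sum of eliminated AFs)`. The
#' eliminated exposures stay in the map (with zero fractions) so that
#' bucket structures stay comparable across scenarios.
#'
#' @param amap an [attribution_map()].
#' @param spec a [scenario_spec()].
#' @return An [attribution_map()] applicable to the counterfactual life
#'   table.
#' @export
counterfactual_attribution <- function(amap, spec) {
  stopifnot(inherits(amap, "attribution_map"), inherits(spec, "scenario_spec"))
  if (!length(spec$eliminated)) return(amap)
  df <- as.data.frame(amap)
  removed <- tapply(df$fraction[df$exposure %in% spec$eliminated],
                    df$cause[df$exposure %in% spec$eliminated], sum)
  keep_share <- 1 - removed[df$cause]
  keep_share[is.na(keep_share)] <- 1
  eliminated <- df$exposure %in% spec$eliminated
  df$fraction[eliminated] <- 0
  rescale <- !eliminated & keep_share > 0
  df$fraction[rescale] <- df$fraction[rescale] / keep_share[rescale]
  df$fraction[!eliminated & keep_share == 0] <- 0  # cause hazard is gone
  attribution_map(df)
}

#' Difference between a counterfactual and a baseline burden summary
#'
#' Per-bucket changes (counterfactual minus baseline) in the risk of
#' premature death, expressed in percentage points, and in mean YLL, in
#' years. Bucket changes sum exactly to the total change.
#'
#' @param baseline,counterfactual `burden_summary` objects with the same
#'   bucket structure.
#' @return Object of class `scenario_comparison` with fields
#'   `risk_change_ppt` and `yll_change` (named per bucket, plus a `total`).
#' @export
decompose_change <- function(baseline, counterfactual) {
  stopifnot(inherits(baseline, "burden_summary"),
            inherits(counterfactual, "burden_summary"))
  if (!identical(baseline$buckets, counterfactual$buckets)) {
    stop("burden summaries have mismatched buckets")
  }
  structure(list(
    baseline = baseline$scenario, counterfactual = counterfactual$scenario,
    buckets = baseline$buckets,
    risk_change_ppt = c(total = 100 * (counterfactual$risk_total - baseline$risk_total),
                        100 * (counterfactual$risk - baseline$risk)),
    yll_change = c(total = counterfactual$yll_total - baseline$yll_total,
                   counterfactual$yll - baseline$yll)
  ), class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("scenario_comparison: %s vs %s\n", x$counterfactual, x$baseline))
  for (b in names(x$risk_change_ppt)) {
    cat(sprintf("  %-14s risk %+6.1f ppt   YLL %+6.2f years\n",
                b, x$risk_change_ppt[b], x$yll_change[b]))
  }
  invisible(x)
}
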