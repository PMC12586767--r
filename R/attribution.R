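#' Exposure-to-cause attributable fractions
#'
#' Encodes `AF(e, c)`, the fraction of deaths from cause `c` assumed
#' attributable to exposure `e`. Fractions lie in `[0, 1]` and, for each
#' cause, sum to at most 1 across exposures, so joint maps remain valid.
#' Pairs not listed have fraction 0.
#'
#' @param fractions either a data.frame with columns `exposure`, `cause`,
#'   `fraction`, or a named list of named numeric vectors, e.g.
#'   `list(tobacco = c(cardiovascular = 0.5))`.
#' @return Object of class `attribution_map` (a validated data.frame).
#' @export
attribution_map <- function(fractions) {
  if (is.list(fractions) && !is.data.frame(fractions)) {
    fractions <- do.call(rbind, lapply(names(fractions), function(e) {
      v <- fractions[[e]]
      data.frame(exposure = e, cause = names(v), fraction = as.numeric(v))
    }))
  }
  stopifnot(is.data.frame(fractions),
            all(c("exposure", "cause", "fraction") %in% names(fractions)))
  fractions <- fractions[c("exposure", "cause", "fraction")]
  if (any(duplicated(fractions[c("exposure", "cause")]))) {
    stop("duplicate (exposure, cause) entry")
  }
  if (any(fractions$fraction < 0 | fractions$fraction > 1)) {
    stop("attributable fractions must lie in [0, 1]")
  }
  per_cause <- tapply(fractions$fraction, fractions$cause, sum)
  if (any(per_cause > 1 + 1e-12)) {
    stop("fractions for a cause sum to more than 1 across exposures: ",
         paste(names(per_cause)[per_cause > 1 + 1e-12], collapse = ", "))
  }
  rownames(fractions) <- NULL
  structure(fractions, class = c("attribution_map", "data.frame"))
}

#' The shipped attributable-fraction assumptions
#'
#' The main-analysis map: 100% of drug-poisoning and viral-hepatitis deaths
#' attributed to illegal drugs; 100% of respiratory-cancer/COPD deaths, 50%
#' of cardiovascular deaths and 30% of other-cancer deaths attributed to
#' tobacco smoking. All other (exposure, cause) pairs are 0.
#'
#' @return An [attribution_map()] with exposures `illegal_drugs` and
#'   `tobacco`.
#' @export
default_attribution <- function() {
  attribution_map(list(
    illegal_drugs = c(drug_poisoning = 1, viral_hepatitis = 1),
    tobacco = c(smoking_specific = 1, cardiovascular = 0.5,
                other_cancers = 0.3)
  ))
}

#' Look up one attributable fraction
#' @param amap an [attribution_map()].
#' @param exposure exposure label.
#' @param cause cause label.
#' @return The fraction, 0 for unlisted pairs.
#' @export
af_lookup <- function(amap, exposure, cause) {
  hit <- amap$exposure == exposure & amap$cause == cause
  if (any(hit)) amap$fraction[hit] else 0
}

#' Exposures declared in an attribution map
#' @param amap an [attribution_map()].
#' @return Character vector of exposure labels.
#' @export
exposures_of <- function(amap) unique(amap$exposure)

# AF as an exposures x causes matrix (zero-filled over the given causes)
af_matrix <- function(amap, causes) {
  exposures <- exposures_of(amap)
  M <- matrix(0, length(exposures), length(causes),
              dimnames = list(exposures, causes))
  keep <- amap$cause %in% causes
  M[cbind(match(amap$exposure[keep], exposures),
          match(amap$cause[keep], causes))] <- amap$fraction[keep]
  M
}

#' Decompose a life table's burden into exposure-attributable buckets
#'
#' For each exposure `e`, the attributable risk is
#' `sum_{a,c} deaths(a, c) * AF(e, c) / radix` and the attributable mean
#' YLL weights the same deaths by the midpoint rule; the `others` bucket is
#' the remainder, so buckets always sum exactly to the totals.
#'
#' @param lt a `life_table`.
#' @param amap an [attribution_map()]; its causes must be a subset of the
#'   life table's causes.
#' @param scenario_label label stored with the summary.
#' @param horizon YLL horizon, default 70.
#' @return Object of class `burden_summary`: total and per-bucket risk of
#'   premature death, total and per-bucket mean YLL, and percent shares of
#'   deaths and of YLL per bucket (buckets: each exposure, then `others`).
#' @export
attribute_burden <- function(lt, amap, scenario_label = "baseline",
                             horizon = HORIZON) {
  stopifnot(inherits(lt, "life_table"), inherits(amap, "attribution_map"))
  unknown <- setdiff(unique(amap$cause), lt$causes)
  if (length(unknown)) {
    stop("attribution map references unknown causes: ",
         paste(unknown, collapse = ", "))
  }
  AF <- af_matrix(amap, lt$causes)
  w <- yll_weights(lt, horizon)
  deaths_e <- AF %*% colSums(lt$deaths_by_cause)            # deaths per exposure
  yll_e <- AF %*% colSums(lt$deaths_by_cause * w)           # YLL per exposure
  risk_total <- premature_death_risk(lt)
  yll_total <- years_of_life_lost(lt, horizon)
  risk <- c(drop(deaths_e) / lt$radix)
  yll <- c(drop(yll_e) / lt$radix)
  risk <- c(risk, others = risk_total - sum(risk))
  yll <- c(yll, others = yll_total - sum(yll))
  share <- function(part, total) if (total > 0) 100 * part / total else 0 * part
  structure(list(scenario = scenario_label,
                 buckets = names(risk),
                 risk_total = risk_total, risk = risk,
                 yll_total = yll_total, yll = yll,
                 share_deaths = share(risk, risk_total),
                 share_yll = share(yll, yll_total),
                 horizon = horizon),
            class = "burden_summary")
}

#' @export
print.burden_summary <- function(x, ...) {
  cat(sprintf("burden_summary '%s' (horizon %d)\n", x$scenario, x$horizon))
  cat(sprintf("  risk of premature death: %.1f%%; mean YLL: %.2f years\n",
              100 * x$risk_total, x$yll_total))
  for (b in x$buckets) {
    cat(sprintf("  %-14s risk %5.1f%% (%4.1f%% of deaths)  YLL %5.2f (%4.1f%%)\n",
                b, 100 * x$risk[b], x$share_deaths[b], x$yll[b], x$share_yll[b]))
  }
  invisible(x)
}

#' Burden summary as a tidy data frame
#' @param summary a `burden_summary`.
#' @return data.frame with one row per bucket plus a `total` row.
#' @export
burden_to_df <- function(summary) {
  stopifnot(inherits(summary, "burden_summary"))
  data.frame(
    scenario = summary$scenario,
    bucket = c("total", summary$buckets),
    risk = c(summary$risk_total, unname(summary$risk)),
    mean_yll = c(summary$yll_total, unname(summary$yll)),
    pct_of_deaths = c(100, unname(summary$share_deaths)),
    pct_of_yll = c(100, unname(summary$share_yll)),
    row.names = NULL
  )
}
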