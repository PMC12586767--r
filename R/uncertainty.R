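# flatten the per-scenario burden summaries (and their changes against the
# baseline) into one named parameter vector for Monte-Carlo bookkeeping
flatten_burdens <- function(burdens) {
  out <- numeric(0)
  grab <- function(prefix, total, per_bucket) {
    v <- c(total = total, per_bucket)
    stats::setNames(v, paste(prefix, names(v), sep = "."))
  }
  for (s in names(burdens)) {
    b <- burdens[[s]]
    out <- c(out,
             grab(paste0(s, ".risk"), b$risk_total, b$risk),
             grab(paste0(s, ".yll"), b$yll_total, b$yll),
             grab(paste0(s, ".pct_deaths"), 100, b$share_deaths),
             grab(paste0(s, ".pct_yll"), 100, b$share_yll))
  }
  if ("baseline" %in% names(burdens)) {
    for (s in setdiff(names(burdens), "baseline")) {
      ch <- decompose_change(burdens$baseline, burdens[[s]])
      out <- c(out,
               stats::setNames(ch$risk_change_ppt,
                               paste(s, "risk_change", names(ch$risk_change_ppt), sep = ".")),
               stats::setNames(ch$yll_change,
                               paste(s, "yll_change", names(ch$yll_change), sep = ".")))
    }
  }
  out
}

# one full pipeline pass on a counts matrix (person-years fixed)
pipeline_pass <- function(D, py, design, amap, scenarios, radix) {
  curves <- lapply(colnames(D), function(cs) fit_pois(D[, cs], py, design, cs))
  names(curves) <- colnames(D)
  curves[[ALL_CAUSE]] <- fit_pois(rowSums(D), py, design, ALL_CAUSE)
  hazards <- apportion_hazards(curves)
  lapply(scenarios, function(sp) scenario_burden(hazards, amap, sp, radix))
}

#' Monte-Carlo confidence intervals for all reported parameters
#'
#' Simulates `n_sims` datasets in which every (age, cause) death count is
#' replaced by a Poisson draw whose mean is the observed count
#' (person-years held fixed), reruns the whole pipeline — rate fitting,
#' hazard apportionment, every scenario's life table and attribution — on
#' each, and reports the empirical 0.025 and 0.975 quantiles of every
#' parameter as a 95% CI. Quantiles use linear interpolation between order
#' statistics (R's default type 7). Reproducible given `seed`: one master
#' seed draws a substream seed per simulation, so results do not depend on
#' how the loop might be chunked.
#'
#' Simulations where a model fit fails are recorded and excluded; more
#' than 1% failures is an error.
#'
#' @param table an [age_cause_table()] (observed counts).
#' @param spline a [spline_spec()].
#' @param amap an [attribution_map()].
#' @param scenarios named list of [scenario_spec()]s; include a scenario
#'   named `baseline` to get change-from-baseline parameters.
#' @param radix life-table radix.
#' @param n_sims number of simulated datasets, default 1000.
#' @param seed integer master seed (required).
#' @param causes declared cause set.
#' @return data.frame of class `uncertainty_result`: one row per parameter
#'   with `point` (from the observed data), `lower`, `upper`, `n_sims`
#'   (successful simulations) and `seed`.
#' @export
monte_carlo <- function(table, spline = spline_spec(),
                        amap = default_attribution(),
                        scenarios = default_scenarios(),
                        radix = 1e5, n_sims = 1000L, seed,
                        causes = default_causes()) {
  stopifnot(inherits(table, "age_cause_table"))
  n_sims <- as.integer(n_sims)
  if (n_sims < 2L) stop("n_sims must be at least 2")
  if (missing(seed)) stop("a seed is required")
  missing_causes <- setdiff(causes, causes_of(table))
  if (length(missing_causes)) {
    stop("table is missing declared categories: ",
         paste(missing_causes, collapse = ", "))
  }
  D <- counts_matrix(table)[, causes, drop = FALSE]
  py <- person_years_vector(table)
  design <- make_design(py, spline)
  point <- flatten_burdens(suppressWarnings(
    pipeline_pass(D, py, design, amap, scenarios, radix)))
  sim_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max, n_sims))
  draws <- matrix(NA_real_, n_sims, length(point),
                  dimnames = list(NULL, names(point)))
  failures <- 0L
  for (i in seq_len(n_sims)) {
    D_star <- with_local_seed(sim_seeds[i], {
      matrix(stats::rpois(length(D), D), nrow(D), ncol(D), dimnames = dimnames(D))
    })
    res <- tryCatch(
      flatten_burdens(suppressWarnings(
        pipeline_pass(D_star, py, design, amap, scenarios, radix))),
      error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else draws[i, ] <- res
  }
  if (failures > 0.01 * n_sims) {
    stop(sprintf("%d of %d simulations failed to fit", failures, n_sims))
  }
  ok <- stats::complete.cases(draws)
  q <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
             probs = c(0.025, 0.975), type = 7)
  structure(data.frame(parameter = names(point), point = unname(point),
                       lower = q[1, ], upper = q[2, ],
                       n_sims = sum(ok), seed = as.integer(seed),
                       row.names = NULL),
            class = c("uncertainty_result", "data.frame"))
}

#' Extract one interval from an uncertainty result
#' @param ci an `uncertainty_result`.
#' @param parameter parameter label, e.g. `"baseline.risk.total"`.
#' @return Named vector `c(point, lower, upper)`.
#' @export
ci_for <- function(ci, parameter) {
  row <- ci[ci$parameter == parameter, ]
  if (nrow(row) != 1) stop("unknown parameter: ", parameter)
  c(point = row$point, lower = row$lower, upper = row$upper)
}
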