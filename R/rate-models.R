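#' Specification of the age-smoothing spline
#'
#' The rate models regress death counts on a natural cubic spline of age
#' (plus an intercept) with an offset for logged person-years. With
#' `degrees_of_freedom = k` the basis has `k` columns: interior knots at
#' the `1/k, ..., (k-1)/k` person-year-weighted quantiles of age, boundary
#' knots at the ends of the age range. `degrees_of_freedom = 0` drops the
#' spline entirely (intercept-only model, i.e. a single flat rate).
#'
#' @param degrees_of_freedom integer >= 0, default 3 (two interior knots).
#' @param basis basis identifier; only `"natural-cubic"` is implemented.
#' @param knot_rule knot placement rule; only `"weighted-quantile"` (ages
#'   weighted by person-years) is implemented.
#' @return Object of class `spline_spec`.
#' @export
spline_spec <- function(degrees_of_freedom = 3L,
                        basis = "natural-cubic",
                        knot_rule = "weighted-quantile") {
  degrees_of_freedom <- as.integer(degrees_of_freedom)
  stopifnot(degrees_of_freedom >= 0)
  basis <- match.arg(basis)
  knot_rule <- match.arg(knot_rule)
  structure(list(degrees_of_freedom = degrees_of_freedom, basis = basis,
                 knot_rule = knot_rule),
            class = "spline_spec")
}

# weighted quantiles by linear interpolation of the cumulative weights
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 1L) return(rep(x, length(probs)))
  cw <- (cumsum(w) - w / 2) / sum(w)  # midpoint rule, symmetric in the weights
  stats::approx(cw, x, xout = probs, rule = 2)$y
}

# spline design matrices at observed ages and on the full prediction grid
make_design <- function(person_years, spec) {
  ages <- model_ages()
  obs <- person_years > 0
  if (!any(obs)) stop("no ages with positive person-years")
  if (spec$degrees_of_freedom == 0L) {
    X_all <- matrix(1, length(ages), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    boundary <- range(ages)
    k <- spec$degrees_of_freedom
    interior <- if (k >= 2L) {
      weighted_quantile(ages, person_years, seq_len(k - 1L) / k)
    }
    interior <- interior[interior > boundary[1] & interior < boundary[2]]
    B <- splines::ns(ages, knots = interior, Boundary.knots = boundary)
    colnames(B) <- paste0("ns", seq_len(ncol(B)))
    X_all <- cbind("(Intercept)" = 1, B)
  }
  list(X_obs = X_all[obs, , drop = FALSE], X_all = X_all, obs = obs)
}

# Poisson IRLS fit of one count series on a prebuilt design
fit_pois <- function(deaths, person_years, design, cause) {
  obs <- design$obs
  y <- deaths[obs]
  if (sum(y) == 0) {
    # no events: the MLE rate is 0; return an epsilon curve and flag it
    warning(sprintf("no deaths for cause '%s'; returning near-zero curve", cause))
    return(rate_curve(cause, rates = rep(1e-12, length(model_ages())),
                      coefficients = NULL, zero_deaths = TRUE))
  }
  fit <- suppressWarnings(stats::glm.fit(
    x = design$X_obs, y = y, family = stats::poisson(),
    offset = log(person_years[obs]),
    control = list(epsilon = 1e-8, maxit = 100)
  ))
  if (!fit$converged) stop(sprintf("Poisson fit did not converge for cause '%s'", cause))
  rates <- as.vector(exp(design$X_all %*% fit$coefficients))
  rate_curve(cause, rates = rates, coefficients = fit$coefficients)
}

# constructor for a fitted (or closed-form) rate curve on the 18-69 grid
rate_curve <- function(cause, rates, coefficients = NULL, zero_deaths = FALSE) {
  ages <- model_ages()
  stopifnot(length(rates) == length(ages))
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("rate curve must be strictly positive and finite at every age")
  }
  structure(list(cause = cause, ages = ages, rates = as.numeric(rates),
                 coefficients = coefficients, zero_deaths = zero_deaths),
            class = "rate_curve")
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("rate_curve '%s': %.2e at age %d to %.2e at age %d%s\n",
              x$cause, x$rates[1], x$ages[1],
              x$rates[length(x$rates)], x$ages[length(x$ages)],
              if (x$zero_deaths) " [no deaths observed]" else ""))
  invisible(x)
}

#' Fit the Poisson spline rate model for one cause
#'
#' Maximum-likelihood Poisson regression of the death count on a natural
#' cubic spline of age with an offset for logged person-years (IRLS,
#' relative-deviance tolerance 1e-8, at most 100 iterations). Ages with
#' zero person-years are excluded from the likelihood but still receive
#' predictions. The predicted rate is `exp(linear predictor)` at each
#' integer age 18-69.
#'
#' @param table an [age_cause_table()].
#' @param cause one of the table's cause labels, or `"all"` for the
#'   all-cause model fitted to counts summed over causes.
#' @param spline a [spline_spec()].
#' @return A `rate_curve`: cause, age grid, predicted rates, coefficients.
#' @export
fit_rate_model <- function(table, cause, spline = spline_spec()) {
  stopifnot(inherits(table, "age_cause_table"), inherits(spline, "spline_spec"))
  D <- counts_matrix(table)
  py <- person_years_vector(table)
  deaths <- if (identical(cause, ALL_CAUSE)) {
    rowSums(D)
  } else {
    if (!cause %in% causes_of(table)) stop("unknown cause: ", cause)
    D[, cause]
  }
  fit_pois(deaths, py, make_design(py, spline), cause)
}

#' Fit rate models for every cause plus the all-cause aggregate
#'
#' @param table an [age_cause_table()] covering all declared categories.
#' @param spline a [spline_spec()].
#' @param causes the declared category set the analysis requires; the table
#'   must carry them all.
#' @return Named list of `rate_curve`s: one per cause plus `"all"`.
#' @export
fit_all <- function(table, spline = spline_spec(), causes = default_causes()) {
  missing_causes <- setdiff(causes, causes_of(table))
  if (length(missing_causes)) {
    stop("table is missing declared categories: ",
         paste(missing_causes, collapse = ", "))
  }
  D <- counts_matrix(table)[, causes, drop = FALSE]
  py <- person_years_vector(table)
  design <- make_design(py, spline)
  curves <- lapply(causes, function(cs) fit_pois(D[, cs], py, design, cs))
  names(curves) <- causes
  curves[[ALL_CAUSE]] <- fit_pois(rowSums(D), py, design, ALL_CAUSE)
  curves
}

#' Additivity check between cause-specific and all-cause curves
#'
#' The cause-specific models are fitted independently of the all-cause
#' model, so their sum only approximates the all-cause curve. This returns
#' the maximum over ages of `|sum of cause rates - all-cause rate| /
#' all-cause rate`; the analysis expects it to be small (about 2%).
#'
#' @param curves list of `rate_curve`s as returned by [fit_all()], i.e. all
#'   cause curves plus the `"all"` curve on the same age grid.
#' @return Maximum relative difference (dimensionless).
#' @export
check_rate_consistency <- function(curves) {
  if (!ALL_CAUSE %in% names(curves)) stop("curves must include the all-cause curve")
  all_curve <- curves[[ALL_CAUSE]]
  cause_curves <- curves[setdiff(names(curves), ALL_CAUSE)]
  grids <- lapply(curves, `[[`, "ages")
  if (!all(vapply(grids, identical, logical(1), y = all_curve$ages))) {
    stop("rate curves are on mismatched age grids")
  }
  cause_sum <- Reduce(`+`, lapply(cause_curves, `[[`, "rates"))
  max(abs(cause_sum - all_curve$rates) / all_curve$rates)
}

#' Observed and modelled rates as a tidy data frame
#'
#' The per-age data behind a rates-by-age figure: empirical rate
#' (deaths / person-years, `NA` where person-years are zero) and the
#' modelled rate for each cause and the all-cause aggregate.
#'
#' @param table an [age_cause_table()].
#' @param curves result of [fit_all()] on that table.
#' @return data.frame with columns age, cause, deaths, person_years,
#'   observed_rate, modelled_rate.
#' @export
rates_to_df <- function(table, curves) {
  D <- counts_matrix(table)
  D <- cbind(D, all = rowSums(D))
  py <- person_years_vector(table)
  do.call(rbind, lapply(names(curves), function(cs) {
    data.frame(age = model_ages(), cause = cs, deaths = D[, cs],
               person_years = as.numeric(py),
               observed_rate = ifelse(py > 0, D[, cs] / py, NA_real_),
               modelled_rate = curves[[cs]]$rates,
               row.names = NULL)
  }))
}
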