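#' Apportion the all-cause hazard into additive cause-specific hazards
#'
#' The cause-specific and all-cause rate models are fitted independently,
#' so the cause curves do not sum exactly to the all-cause curve. For
#' life-table work we use the all-cause model as the governing hazard and
#' split it across causes in the ratio of the modelled cause rates:
#' `h(a, c) = m_all(a) * m_c(a) / sum_c m_c(a)`. The result is additive by
#' construction (`rowSums(h) = m_all`), so baseline and counterfactual
#' tables stay internally consistent.
#'
#' @param curves result of [fit_all()]: cause curves plus `"all"`.
#' @return Numeric matrix, ages 18-69 by cause, deaths per person-year.
#' @export
apportion_hazards <- function(curves) {
  if (!ALL_CAUSE %in% names(curves)) stop("curves must include the all-cause curve")
  cause_names <- setdiff(names(curves), ALL_CAUSE)
  m <- vapply(curves[cause_names], `[[`, numeric(length(model_ages())), "rates")
  h <- m / rowSums(m) * curves[[ALL_CAUSE]]$rates
  rownames(h) <- model_ages()
  h
}

#' Period life table with deaths decomposed by cause
#'
#' Follows a closed hypothetical cohort of `radix` people from exact age 18
#' to age 70 under the supplied hazards. Within each one-year interval the
#' hazard is constant, so the probability of death is
#' `q_a = 1 - exp(-m_all(a))` (the default conversion; the classical
#' actuarial approximation `m / (1 + m/2)` is available for sensitivity).
#' Deaths in the interval are split across causes in proportion to the
#' cause-specific hazards.
#'
#' @param all_cause all-cause `rate_curve` (or `NULL` to use the row sums
#'   of the cause hazards, which is the same thing after apportionment).
#' @param cause_curves named list of cause `rate_curve`s, or a numeric
#'   age-by-cause hazard matrix such as [apportion_hazards()] returns.
#' @param radix starting cohort size, default 100 000.
#' @param conversion hazard-to-probability rule, `"exponential"` (default)
#'   or `"actuarial"`.
#' @return Object of class `life_table` with fields `radix`, `ages`,
#'   `survivors` (at the start of each age interval), `deaths_total`,
#'   `deaths_by_cause` (age-by-cause matrix), `cumulative_risk` (fraction
#'   of the radix dead by the end of each interval), and `causes`.
#' @export
build_life_table <- function(all_cause = NULL, cause_curves, radix = 1e5,
                             conversion = c("exponential", "actuarial")) {
  conversion <- match.arg(conversion)
  if (!is.numeric(radix) || length(radix) != 1 || radix <= 0) {
    stop("radix must be a single positive number")
  }
  ages <- model_ages()
  if (is.matrix(cause_curves)) {
    h <- cause_curves
  } else {
    m <- vapply(cause_curves, `[[`, numeric(length(ages)), "rates")
    h <- if (is.null(all_cause)) m else m / rowSums(m) * all_cause$rates
  }
  if (nrow(h) != length(ages)) stop("hazards must cover ages 18-69")
  if (any(!is.finite(h)) || any(h < 0)) {
    stop("hazards must be finite and non-negative")
  }
  m_all <- rowSums(h)
  q <- switch(conversion,
              exponential = 1 - exp(-m_all),
              actuarial = m_all / (1 + m_all / 2))
  survivors <- numeric(length(ages))
  deaths_total <- numeric(length(ages))
  l <- radix
  for (i in seq_along(ages)) {
    survivors[i] <- l
    deaths_total[i] <- l * q[i]
    l <- l - deaths_total[i]
  }
  share <- h / ifelse(m_all > 0, m_all, 1)  # cause split; 0/0 -> 0
  share[m_all == 0, ] <- 0
  deaths_by_cause <- share * deaths_total
  dimnames(deaths_by_cause) <- list(ages, colnames(h))
  structure(list(radix = radix, ages = ages, survivors = survivors,
                 deaths_total = deaths_total,
                 deaths_by_cause = deaths_by_cause,
                 cumulative_risk = cumsum(deaths_total) / radix,
                 causes = colnames(h), conversion = conversion),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("life_table: radix %s, ages %d-%d, %d causes\n",
              format(x$radix, big.mark = " ", scientific = FALSE),
              min(x$ages), max(x$ages),
              length(x$causes)))
  cat(sprintf("  risk of death before %d: %.1f%%; mean YLL %.2f years\n",
              max(x$ages) + 1, 100 * premature_death_risk(x),
              years_of_life_lost(x)))
  invisible(x)
}

#' Risk of death before the end of the modelled age range
#'
#' @param lt a `life_table`.
#' @return Fraction of the radix dead before age 70, in `[0, 1]`.
#' @export
premature_death_risk <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  sum(lt$deaths_total) / lt$radix
}

# midpoint-of-interval YLL weight per age: a death during [a, a+1) is timed
# at a + 0.5 and loses horizon - a - 0.5 years
yll_weights <- function(lt, horizon) {
  if (horizon <= min(lt$ages)) stop("horizon must exceed the first modelled age")
  if (horizon < max(lt$ages) + 1) {
    stop("horizon must lie at or above the end of the modelled age range")
  }
  horizon - lt$ages - 0.5
}

#' Mean years-of-life lost per person before the horizon
#'
#' Each death in age interval `[a, a+1)` contributes `horizon - a - 0.5`
#' years (a death at age 69 loses 0.5 years to a horizon of 70, at 68 loses
#' 1.5 years, and so on); the mean is taken over the whole radix cohort,
#' including those who survive to the horizon.
#'
#' @param lt a `life_table`.
#' @param horizon age to which lost years are counted, default 70.
#' @return Mean YLL per person, in years.
#' @export
years_of_life_lost <- function(lt, horizon = HORIZON) {
  stopifnot(inherits(lt, "life_table"))
  sum(lt$deaths_total * yll_weights(lt, horizon)) / lt$radix
}

#' Cause-decomposed mean years-of-life lost
#'
#' @inheritParams years_of_life_lost
#' @return Named vector: mean YLL per person contributed by each cause.
#' @export
yll_by_cause <- function(lt, horizon = HORIZON) {
  stopifnot(inherits(lt, "life_table"))
  colSums(lt$deaths_by_cause * yll_weights(lt, horizon)) / lt$radix
}

#' Life table as a tidy data frame
#'
#' One row per (age, cause) plus a `total` row per age: survivors at the
#' start of the interval, deaths in the interval, and cumulative risk —
#' the data behind a cumulative-mortality figure.
#'
#' @param lt a `life_table`.
#' @return data.frame with columns age, cause, survivors, deaths,
#'   cumulative_risk.
#' @export
lifetable_to_df <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  per_cause <- do.call(rbind, lapply(lt$causes, function(cs) {
    data.frame(age = lt$ages, cause = cs, survivors = lt$survivors,
               deaths = lt$deaths_by_cause[, cs],
               cumulative_risk = cumsum(lt$deaths_by_cause[, cs]) / lt$radix,
               row.names = NULL)
  }))
  total <- data.frame(age = lt$ages, cause = "total", survivors = lt$survivors,
                      deaths = lt$deaths_total,
                      cumulative_risk = lt$cumulative_risk, row.names = NULL)
  rbind(total, per_cause)
}
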