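test_that("null hazards leave the cohort intact", {
  h <- flat_hazards(c(a = 0, b = 0))
  lt <- build_life_table(cause_curves = h)
  expect_equal(lt$survivors, rep(1e5, length(ages)))
  expect_equal(premature_death_risk(lt), 0)
  expect_equal(years_of_life_lost(lt), 0)
  expect_equal(max(lt$cumulative_risk), 0)
})

test_that("constant hazard reproduces the closed-form risk", {
  for (m in c(0.001, 0.01, 0.05)) {
    lt <- build_life_table(cause_curves = flat_hazards(c(only = m)))
    expect_equal(premature_death_risk(lt), 1 - exp(-52 * m), tolerance = 1e-12)
  }
  # overwhelming hazard: everyone dies
  lt <- build_life_table(cause_curves = flat_hazards(c(only = 10)))
  expect_gt(premature_death_risk(lt), 0.999999)
  # actuarial conversion follows its own closed form
  m <- 0.02
  lt <- build_life_table(cause_curves = flat_hazards(c(only = m)),
                         conversion = "actuarial")
  expect_equal(premature_death_risk(lt), 1 - (1 - m / (1 + m / 2))^52,
               tolerance = 1e-12)
})

test_that("conservation, additivity and scale invariance hold", {
  w <- default_world()
  for (radix in c(1, 1e5, 1e7)) {
    lt <- build_life_table(cause_curves = w$true_hazards, radix = radix)
    # survivors in = survivors out + deaths, at every age
    l_next <- c(lt$survivors[-1], radix - sum(lt$deaths_total))
    expect_equal(lt$survivors - lt$deaths_total, l_next, tolerance = 1e-12)
    # cause decomposition sums to the total at every age
    expect_equal(unname(rowSums(lt$deaths_by_cause)), lt$deaths_total,
                 tolerance = 1e-9)
    # radix balances
    expect_equal(sum(lt$deaths_total) + l_next[length(l_next)], radix,
                 tolerance = 1e-9)
    expect_true(all(diff(lt$survivors) <= 0))
    expect_true(all(diff(lt$cumulative_risk) >= 0))
    expect_true(all(lt$cumulative_risk >= 0 & lt$cumulative_risk <= 1))
  }
  # risk and mean YLL do not depend on the radix
  lt1 <- build_life_table(cause_curves = w$true_hazards, radix = 1)
  lt2 <- build_life_table(cause_curves = w$true_hazards, radix = 1e7)
  expect_equal(premature_death_risk(lt1), premature_death_risk(lt2))
  expect_equal(years_of_life_lost(lt1), years_of_life_lost(lt2))
})

test_that("deaths are apportioned in the ratio of modelled cause rates", {
  h <- flat_hazards(c(a = 0.03, b = 0.01))
  lt <- build_life_table(cause_curves = h)
  expect_equal(lt$deaths_by_cause[, "a"], 3 * lt$deaths_by_cause[, "b"],
               tolerance = 1e-12)
  # via rate curves + all-cause curve: apportionment tolerates inexact sums
  curves <- list(
    a = lifedecomp:::rate_curve("a", rep(0.03, length(ages))),
    b = lifedecomp:::rate_curve("b", rep(0.01, length(ages))),
    all = lifedecomp:::rate_curve("all", rep(0.041, length(ages)))
  )
  hz <- apportion_hazards(curves)
  expect_equal(unname(rowSums(hz)), curves$all$rates)  # additive by construction
  expect_equal(unname(hz[, "a"] / hz[, "b"]), rep(3, length(ages)))
})

test_that("YLL uses midpoint timing against the age-70 horizon", {
  # a single death at age 69 loses half a year
  d <- rep(0, length(ages)); d[ages == 69] <- 1
  lt <- manual_life_table(d, radix = 1)
  expect_equal(years_of_life_lost(lt), 0.5)
  # hand sum: 100 deaths at 68 (1.5 y each) + 100 at 69 (0.5 y), radix 200
  d <- rep(0, length(ages)); d[ages == 68] <- 100; d[ages == 69] <- 100
  lt <- manual_life_table(d, radix = 200)
  expect_equal(years_of_life_lost(lt), (100 * 1.5 + 100 * 0.5) / 200)
  # a death at 18 loses 51.5 years
  d <- rep(0, length(ages)); d[ages == 18] <- 1
  expect_equal(years_of_life_lost(manual_life_table(d, radix = 1)), 51.5)
  expect_error(years_of_life_lost(lt, horizon = 18), "horizon")
  expect_error(years_of_life_lost(lt, horizon = 69), "horizon")
})

test_that("an individual-level microsimulation agrees with the life table", {
  w <- default_world()
  lt <- build_life_table(cause_curves = w$true_hazards, radix = 1e5)
  n <- 1e6
  ms <- microsim(w$true_hazards, n = n, seed = 424)

  # risk within 3 binomial standard errors
  p <- premature_death_risk(lt)
  expect_lt(abs(ms$risk - p), 3 * sqrt(p * (1 - p) / n))

  # cause split within 3 SE per cause
  frac <- colSums(lt$deaths_by_cause) / lt$radix
  for (cs in names(frac)) {
    se <- sqrt(frac[cs] * (1 - frac[cs]) / n)
    expect_lt(abs(ms$deaths_by_cause[cs] / n - frac[cs]), 3 * se)
  }

  # mean YLL within 3 SE (per-person YLL variance from the life table)
  yll <- years_of_life_lost(lt)
  w_age <- 70 - ages - 0.5
  second_moment <- sum(lt$deaths_total * w_age^2) / lt$radix
  se_yll <- sqrt((second_moment - yll^2) / n)
  expect_lt(abs(ms$mean_yll - yll), 3 * se_yll)
})

test_that("raising any cause's hazard weakly raises risk and YLL", {
  w <- default_world()
  base_lt <- build_life_table(cause_curves = w$true_hazards)
  for (cs in colnames(w$true_hazards)) {
    h <- w$true_hazards
    h[, cs] <- h[, cs] * 1.25
    lt <- build_life_table(cause_curves = h)
    expect_gte(premature_death_risk(lt), premature_death_risk(base_lt))
    expect_gte(years_of_life_lost(lt), years_of_life_lost(base_lt))
  }
})

test_that("life-table construction validates its inputs", {
  h <- flat_hazards(c(a = 0.01))
  expect_error(build_life_table(cause_curves = h, radix = 0), "radix")
  expect_error(build_life_table(cause_curves = h, radix = -5), "radix")
  h[3, 1] <- NA
  expect_error(build_life_table(cause_curves = h), "finite")
  h[3, 1] <- -0.01
  expect_error(build_life_table(cause_curves = h), "non-negative")
})

test_that("the tidy export matches the table", {
  w <- default_world()
  lt <- build_life_table(cause_curves = w$true_hazards)
  df <- lifetable_to_df(lt)
  tot <- df[df$cause == "total", ]
  expect_equal(tot$deaths, lt$deaths_total)
  expect_equal(tot$cumulative_risk, lt$cumulative_risk)
  expect_setequal(unique(df$cause), c("total", lt$causes))
  # per-cause cumulative risks end at the cause-specific lifetime risks
  last <- df[df$age == 69 & df$cause != "total", ]
  expect_equal(sum(last$cumulative_risk), premature_death_risk(lt),
               tolerance = 1e-9)
})
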