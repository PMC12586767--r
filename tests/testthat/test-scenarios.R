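test_that("elimination transforms the apportioned hazards as specified", {
  w <- default_world()
  h <- apportion_hazards(fit_all(w$table))
  amap <- default_attribution()

  # empty elimination set: identity
  expect_identical(apply_elimination(h, amap, scenario_spec("base")), h)

  # eliminating drugs zeroes poisoning and hepatitis, leaves the rest
  h_d <- apply_elimination(h, amap, scenario_spec("d", "illegal_drugs"))
  expect_true(all(h_d[, "drug_poisoning"] == 0))
  expect_true(all(h_d[, "viral_hepatitis"] == 0))
  for (cs in c("smoking_specific", "other_cancers", "cardiovascular", "other")) {
    expect_equal(h_d[, cs], h[, cs])
  }

  # eliminating tobacco: smoking-specific to 0, cardiovascular halved,
  # other cancers scaled by 0.7, at every age
  h_t <- apply_elimination(h, amap, scenario_spec("t", "tobacco"))
  expect_true(all(h_t[, "smoking_specific"] == 0))
  expect_equal(h_t[, "cardiovascular"], 0.5 * h[, "cardiovascular"])
  expect_equal(h_t[, "other_cancers"], 0.7 * h[, "other_cancers"])
  expect_equal(h_t[, "drug_poisoning"], h[, "drug_poisoning"])

  # both: intersection of the two transforms
  h_b <- apply_elimination(h, amap,
                           scenario_spec("b", c("illegal_drugs", "tobacco")))
  expect_equal(h_b, apply_elimination(h_d, amap, scenario_spec("t", "tobacco")))

  expect_error(apply_elimination(h, amap, scenario_spec("x", "alcohol")),
               "undeclared")
})

test_that("counterfactual attribution rescales to the remaining hazard", {
  amap <- default_attribution()
  # eliminated exposure drops to zero; untouched causes keep their fractions
  cf <- counterfactual_attribution(amap, scenario_spec("t", "tobacco"))
  expect_equal(af_lookup(cf, "tobacco", "cardiovascular"), 0)
  expect_equal(af_lookup(cf, "tobacco", "smoking_specific"), 0)
  expect_equal(af_lookup(cf, "illegal_drugs", "drug_poisoning"), 1)
  # shared cause: the surviving exposure's share of the remaining hazard
  joint <- attribution_map(list(e1 = c(x = 0.4), e2 = c(x = 0.4)))
  cf2 <- counterfactual_attribution(joint, scenario_spec("g", "e1"))
  expect_equal(af_lookup(cf2, "e2", "x"), 0.4 / 0.6)
  expect_equal(af_lookup(cf2, "e1", "x"), 0)
  # empty scenario is the identity
  expect_identical(counterfactual_attribution(amap, scenario_spec("b")), amap)
})

test_that("competing-risks ordering holds across random synthetic cohorts", {
  amap <- default_attribution()
  scens <- default_scenarios()
  for (seed in c(101, 202, 303)) {
    tab <- generate_counts(seed = seed)
    burdens <- lapply(scens, function(sp) {
      run_scenario(tab, amap = amap, spec = sp, causes = causes_of(tab))
    })
    r <- vapply(burdens, `[[`, numeric(1), "risk_total")
    expect_lte(r[["eliminate_both"]],
               min(r[["eliminate_drugs"]], r[["eliminate_tobacco"]]))
    expect_lte(max(r[["eliminate_drugs"]], r[["eliminate_tobacco"]]),
               r[["baseline"]])
  }
})

test_that("an eliminated exposure carries zero counterfactual burden", {
  w <- default_world()
  b_d <- run_scenario(w$table, spec = scenario_spec("d", "illegal_drugs"))
  expect_equal(unname(b_d$risk["illegal_drugs"]), 0)
  expect_equal(unname(b_d$yll["illegal_drugs"]), 0)
  b_t <- run_scenario(w$table, spec = scenario_spec("t", "tobacco"))
  expect_equal(unname(b_t$risk["tobacco"]), 0)
  expect_equal(unname(b_t$yll["tobacco"]), 0)
})

test_that("non-eliminated buckets never shrink when an exposure goes", {
  # survivors of the eliminated causes stay at risk of everything else,
  # so the remaining buckets' deaths (and risk) can only grow
  w <- default_world()
  base <- run_scenario(w$table)
  for (gone in list("illegal_drugs", "tobacco", c("illegal_drugs", "tobacco"))) {
    cf <- run_scenario(w$table, spec = scenario_spec("cf", gone))
    for (b in setdiff(base$buckets, gone)) {
      expect_gte(cf$risk[[b]], base$risk[[b]])
      expect_gte(cf$yll[[b]], base$yll[[b]])
    }
  }
})

test_that("decompose_change differences buckets exactly", {
  w <- default_world()
  base <- run_scenario(w$table)
  expect_identical_change_zero <- function(ch) {
    expect_true(all(abs(ch$risk_change_ppt) < 1e-12))
    expect_true(all(abs(ch$yll_change) < 1e-12))
  }
  expect_identical_change_zero(decompose_change(base, base))

  cf <- run_scenario(w$table, spec = scenario_spec("d", "illegal_drugs"))
  ch <- decompose_change(base, cf)
  expect_equal(unname(ch$risk_change_ppt["total"]),
               sum(ch$risk_change_ppt[names(ch$risk_change_ppt) != "total"]),
               tolerance = 1e-9)
  expect_equal(unname(ch$yll_change["total"]),
               sum(ch$yll_change[names(ch$yll_change) != "total"]),
               tolerance = 1e-9)
  # the eliminated bucket loses exactly its baseline burden
  expect_equal(unname(ch$risk_change_ppt["illegal_drugs"]),
               -100 * unname(base$risk["illegal_drugs"]), tolerance = 1e-9)

  other <- base; other$buckets <- c("x", "y")
  expect_error(decompose_change(base, other), "mismatched")
})

test_that("moving attributable deaths younger raises YLL, not the count", {
  # same number of deaths for cause "x", concentrated young vs old
  young <- rep(0, length(ages)); young[ages %in% 25:29] <- 20
  old <- rep(0, length(ages)); old[ages %in% 60:64] <- 20
  amap <- attribution_map(list(e = c(x = 1)))
  b_young <- attribute_burden(manual_life_table(young, radix = 1e3,
                                                causes = "x"), amap)
  b_old <- attribute_burden(manual_life_table(old, radix = 1e3,
                                              causes = "x"), amap)
  expect_equal(b_young$risk[["e"]], b_old$risk[["e"]])
  expect_gt(b_young$yll[["e"]], b_old$yll[["e"]])
})

test_that("run_scenario is deterministic end to end", {
  w <- default_world()
  sp <- scenario_spec("t", "tobacco")
  b1 <- run_scenario(w$table, spec = sp)
  b2 <- run_scenario(w$table, spec = sp)
  expect_identical(b1, b2)
})
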