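# Decision tree: screening detection, treatment-adjusted birth timing,
# stillbirth and pregnancy-phase costs.

test_that("detection probabilities follow the tree arithmetic", {
  p <- base_params()
  one <- stratum_mix("one_step", p)
  two <- stratum_mix("two_step", p)
  none <- stratum_mix("no_screen", p)

  expect_equal(attr(one, "screen_pos_le25"), 0.044)
  expect_equal(attr(one, "screen_pos_le15"), 0.044 * 0.468)  # 0.020592
  expect_equal(attr(two, "screen_pos_le25"), 0.044 + 0.956 * 0.076)
  expect_equal(attr(two, "screen_pos_le15"),
               0.044 * 0.468 + 0.956 * 0.076 * 0.377)
  expect_equal(attr(none, "screen_pos_le25"), 0)

  # cell masses are a distribution; treated-as marginal puts all undetected
  # mass with expectant management
  for (m in list(one, two, none)) {
    expect_equal(sum(m$prob), 1, tolerance = 1e-12)
    expect_equal(sum(stratum_marginal(m)), 1, tolerance = 1e-12)
  }
  expect_equal(unname(stratum_marginal(none)), c(0, 0, 1))
  expect_equal(unname(stratum_marginal(one)[1:2]),
               c(0.044 * 0.468, 0.044 * 0.532))
})

test_that("detection is monotone: two-step >= one-step >= no screening", {
  p <- base_params()
  set.seed(101)
  for (i in 1:25) {
    q <- p
    q <- override_parameter(q, "screening.p_s1_le25", runif(1, 0.01, 0.3))
    q <- override_parameter(q, "screening.p_s1_le15_given_le25", runif(1))
    q <- override_parameter(q, "screening.p_s2_le25_given_s1_neg", runif(1, 0, 0.3))
    q <- override_parameter(q, "screening.p_s2_le15_given_le25_s1neg", runif(1))
    m0 <- stratum_mix("no_screen", q)
    m1 <- stratum_mix("one_step", q)
    m2 <- stratum_mix("two_step", q)
    expect_gte(attr(m2, "screen_pos_le25"), attr(m1, "screen_pos_le25"))
    expect_gte(attr(m1, "screen_pos_le25"), attr(m0, "screen_pos_le25"))
    expect_gte(attr(m2, "screen_pos_le15"), attr(m1, "screen_pos_le15"))
    expect_gte(attr(m1, "screen_pos_le15"), attr(m0, "screen_pos_le15"))
  }
})

test_that("treatment scales preterm mass by uptake-blended relative risks", {
  baseline <- c(0.04, 0.03, 0.06, 0.497, 0.373)
  names(baseline) <- twincua:::GA_LEVELS
  rr <- setNames(c(0.53, 0.71, 0.64, 1.02), twincua:::PRETERM_LEVELS)

  expect_equal(adjusted_birth_timing(baseline, NULL), baseline)
  expect_equal(adjusted_birth_timing(baseline, rr, uptake = 0), baseline)
  expect_equal(adjusted_birth_timing(baseline, rr / rr), baseline)

  adj <- adjusted_birth_timing(baseline, rr, uptake = 1)
  expect_equal(unname(adj["ga_le28"]), 0.04 * 0.53)  # 0.0212
  expect_equal(sum(adj), 1, tolerance = 1e-14)
  # residual goes to term
  expect_equal(unname(adj["ga_gt37"]), 1 - sum(baseline[1:4] * rr))

  # half uptake blends toward no effect
  half <- adjusted_birth_timing(baseline, rr, uptake = 0.5)
  expect_equal(unname(half["ga_le28"]), 0.04 * (0.5 * 0.53 + 0.5))

  # inconsistent inputs: preterm mass above 1
  heavy <- c(0.5, 0.3, 0.15, 0.04, 0.01)
  expect_error(adjusted_birth_timing(heavy, rr * 4), "exceed 1")
})

test_that("strategy birth timing is a valid prevalence-weighted mixture", {
  p <- base_params()
  for (s in c("no_screen", "one_step", "two_step")) {
    bt <- strategy_birth_timing(s, p)
    expect_equal(sum(bt), 1, tolerance = 1e-12)
    expect_true(all(bt >= 0))
  }
  # no screening: hand-computed 3-term mixture of stratum baselines
  prev <- attr(stratum_mix("no_screen", p), "prevalence")
  manual <- as.numeric(prev %*% p$values$baseline_birth_timing)
  expect_equal(unname(strategy_birth_timing("no_screen", p)), manual,
               tolerance = 1e-12)

  # with the published (risk-reducing) RRs, screening shifts mass out of the
  # extreme-preterm category: two-step < one-step < none
  b0 <- strategy_birth_timing("no_screen", p)["ga_le28"]
  b1 <- strategy_birth_timing("one_step", p)["ga_le28"]
  b2 <- strategy_birth_timing("two_step", p)["ga_le28"]
  expect_lt(b2, b1)
  expect_lt(b1, b0)

  # all relative risks 1: the three strategies coincide
  q <- null_effect_params(p)
  expect_equal(strategy_birth_timing("one_step", q),
               strategy_birth_timing("no_screen", q), tolerance = 1e-12)
  expect_equal(strategy_birth_timing("two_step", q),
               strategy_birth_timing("no_screen", q), tolerance = 1e-12)
})

test_that("stillbirth rate is the birth-timing/stillbirth dot product", {
  p <- base_params()
  expect_equal(stillbirth_rate("no_screen", p,
                               birth_timing = rep(0.2, 5)) ,
               1000 * 0.2 * sum(p$values$stillbirth_prob))
  q <- p
  sb <- c(0.01, 0.008, 0.006, 0.005, 0.006)
  for (i in 1:5)
    q <- override_parameter(q, paste0("stillbirth_prob.",
                                      twincua:::GA_LEVELS[i]), sb[i])
  expect_equal(stillbirth_rate("no_screen", q, birth_timing = rep(0.2, 5)), 7.0)
  for (i in 1:5)
    q <- override_parameter(q, paste0("stillbirth_prob.",
                                      twincua:::GA_LEVELS[i]), 0)
  expect_equal(stillbirth_rate("two_step", q), 0)
})

test_that("pregnancy cost components follow their closed forms", {
  p <- base_params()
  pc0 <- pregnancy_costs("no_screen", p)
  expect_equal(unname(pc0[c("ultrasound", "progesterone", "cerclage")]),
               c(0, 0, 0))
  expect_equal(unname(pc0["total"]), sum(pc0[setdiff(names(pc0), "total")]))

  # scans: configured count times unit cost
  q <- override_parameter(p, "costs.ultrasound_per_scan", 16)
  q$values$n_scans[["one_step"]] <- 6
  expect_equal(unname(pregnancy_costs("one_step", q)["ultrasound"]), 96)

  # birth cost: Cesarean-rate weighting
  expect_equal(unname(pc0["birth"]),
               0.6 * p$values$costs$cesarean_birth +
                 0.4 * p$values$costs$vaginal_birth)

  # cerclage: procedure cost times <=15 mm detection times uptake
  expect_equal(unname(pregnancy_costs("two_step", p)["cerclage"]),
               p$values$costs$cerclage_procedure *
                 attr(stratum_mix("two_step", p), "screen_pos_le15"))

  # NICU: flat $100,000, admission only <= 34+0 weeks, twins doubled
  q <- p
  adm <- c(1, 1, 1, 0, 0)
  for (i in 1:5) {
    q <- override_parameter(q, paste0("nicu_admission.",
                                      twincua:::GA_LEVELS[i]), adm[i])
    q <- override_parameter(q, paste0("costs.nicu_per_admission.",
                                      twincua:::GA_LEVELS[i]), 1e5)
  }
  bt <- strategy_birth_timing("no_screen", q)
  expect_equal(unname(pregnancy_costs("no_screen", q)["nicu"]),
               2 * sum(bt[1:3]) * 1e5)

  # with null treatment effects only screening/treatment costs differ
  q <- null_effect_params(p)
  c0 <- pregnancy_costs("no_screen", q)
  c2 <- pregnancy_costs("two_step", q)
  expect_equal(c0[["nicu"]], c2[["nicu"]], tolerance = 1e-12)
  expect_equal(c0[["birth"]], c2[["birth"]])
  expect_gt(c2[["total"]], c0[["total"]])
})
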