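# Lifetime cohort model: mortality schedules, utility blending, survival,
# discounting.

test_that("mortality schedules apply hazard ratios on the hazard scale", {
  p <- base_params()
  # term category: schedule equals the lifetable at every age
  expect_equal(mortality_schedule("ga_gt37", p), p$values$lifetable)

  # closed form: q = 0.01, HR = 2 -> 1 - 0.99^2 = 0.0199
  q <- p
  q$values$lifetable[] <- 0.01
  q$values$hazard_ratio[, "ga_le28"] <- 2
  sched <- mortality_schedule("ga_le28", q)
  expect_equal(unname(sched[["a0"]]), 1 - 0.99^2)
  expect_equal(unname(sched[["a45"]]), 0.0199)
  # equal hazards from age 46 onwards
  expect_equal(unname(sched[["a50"]]), 0.01)
  expect_equal(sched[47:100], q$values$lifetable[47:100])

  expect_error({
    bad <- p
    bad$values$hazard_ratio[1, "ga_le28"] <- -1
    mortality_schedule("ga_le28", bad)
  }, "hazard ratios")
})

test_that("utility blending is the NSI-weighted linear mix", {
  expect_equal(blend_utility(0.6, 0.9, 0), 0.9)
  expect_equal(blend_utility(0.6, 0.9, 1), 0.6)
  expect_equal(blend_utility(0.6, 0.9, 0.25), 0.825)
  expect_equal(blend_utility(c(0.5, 0.6), c(0.8, 0.9), 0.5), c(0.65, 0.75))
  expect_error(blend_utility(0.6, 0.9, 2))
})

test_that("cohort survival and rewards match closed forms", {
  p <- base_params()

  # immortal cohort, utility 1, no discounting: one reward per cycle
  q <- p
  q$values$lifetable[] <- 0
  q$values$hazard_ratio[] <- 1
  q$values$utility[] <- 1
  q <- override_parameter(q, "discount_rate", 0)
  res <- run_cstm("ga_gt37", q)
  expect_equal(res$discounted_qalys, 101)
  expect_equal(res$life_expectancy, 101)
  expect_true(all(res$survival_curve == 1))

  # constant death probability: geometric annuity
  for (mort in c(0.02, 0.1)) {
    q2 <- q
    q2$values$lifetable[] <- mort
    res <- run_cstm("ga_gt37", q2)
    expect_equal(res$discounted_qalys, (1 - (1 - mort)^101) / mort,
                 tolerance = 1e-10)
    expect_true(all(diff(res$survival_curve) <= 0))
    expect_equal(unname(res$survival_curve[["a0"]]), 1)
  }

  # 1.5%/yr discounting of an immortal cohort: standard discrete annuity
  q3 <- q
  q3 <- override_parameter(q3, "discount_rate", 0.015)
  res <- run_cstm("ga_gt37", q3)
  v <- 1 / 1.015
  expect_equal(res$discounted_qalys, (1 - v^101) / (1 - v), tolerance = 1e-10)

  # constant cost: same annuity scaled by the cost
  q4 <- q3
  q4$values$annual_cost[] <- 500
  q4 <- override_parameter(q4, "annual_cost_after9", 500)
  res <- run_cstm("ga_gt37", q4)
  expect_equal(res$discounted_cost, 500 * (1 - v^101) / (1 - v),
               tolerance = 1e-8)
})

test_that("discounting is monotone and survival dominance carries through", {
  p <- base_params()
  rates <- c(0, 0.015, 0.03, 0.05)
  qalys <- vapply(rates, function(r)
    run_cstm("ga_34_37", override_parameter(p, "discount_rate", r))$discounted_qalys,
    numeric(1))
  costs <- vapply(rates, function(r)
    run_cstm("ga_34_37", override_parameter(p, "discount_rate", r))$discounted_cost,
    numeric(1))
  expect_true(all(diff(qalys) < 0))
  expect_true(all(diff(costs) < 0))

  # pointwise higher mortality (earlier GA categories) => pointwise lower
  # survival and shorter life expectancy
  res <- lapply(twincua:::GA_LEVELS, run_cstm, params = p)
  surv <- vapply(res, `[[`, numeric(101), "survival_curve")
  le <- vapply(res, `[[`, numeric(1), "life_expectancy")
  for (g in 1:4) {
    expect_true(all(surv[, g] <= surv[, 5] + 1e-15))
    expect_lt(le[g], le[5])
  }
  expect_true(all(le <= 101))
})

test_that("half-cycle correction shifts QALYs by less than one utility-year", {
  p <- base_params()
  hc <- p
  hc$values$options$half_cycle <- TRUE
  for (g in c("ga_le28", "ga_gt37")) {
    a <- run_cstm(g, p)
    b <- run_cstm(g, hc)
    expect_true(abs(a$discounted_qalys - b$discounted_qalys) < 1)
    expect_lt(b$discounted_qalys, a$discounted_qalys)
    expect_equal(a$life_expectancy, b$life_expectancy)
  }
})
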