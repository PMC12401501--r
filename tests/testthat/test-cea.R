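# Strategy aggregation, incremental statistics, PSA and CEAC.

test_that("strategy outcomes aggregate the tree and cohort consistently", {
  p <- base_params()
  out <- evaluate_strategy("two_step", p)

  # spreadsheet oracle: birth-timing-weighted sum of the five cohort runs
  bt <- strategy_birth_timing("two_step", p)
  cstm <- lapply(twincua:::GA_LEVELS, run_cstm, params = p)
  expect_equal(out$total_qalys,
               2 * sum(bt * vapply(cstm, `[[`, numeric(1), "discounted_qalys")),
               tolerance = 1e-12)
  expect_equal(out$lifetime_cost,
               2 * sum(bt * vapply(cstm, `[[`, numeric(1), "discounted_cost")),
               tolerance = 1e-12)
  expect_equal(out$life_expectancy,
               2 * sum(bt * vapply(cstm, `[[`, numeric(1), "life_expectancy")),
               tolerance = 1e-12)
  expect_equal(out$total_cost, out$costs[["total"]] + out$lifetime_cost)

  # PTB proportions are nested cumulative sums
  expect_equal(out$ptb_le28, unname(bt[1]))
  expect_equal(out$ptb_le32, unname(sum(bt[1:2])))
  expect_equal(out$ptb_le34, unname(sum(bt[1:3])))
  expect_true(out$ptb_le28 <= out$ptb_le32 && out$ptb_le32 <= out$ptb_le34)
})

test_that("post-birth outcomes scale linearly with the twin multiplier", {
  p <- base_params()
  p1 <- override_parameter(p, "twin_multiplier", 1)
  o1 <- evaluate_strategy("one_step", p1)
  o2 <- evaluate_strategy("one_step", p)
  expect_equal(o2$total_qalys, 2 * o1$total_qalys, tolerance = 1e-12)
  expect_equal(o2$lifetime_cost, 2 * o1$lifetime_cost, tolerance = 1e-12)
  expect_equal(o2$life_expectancy, 2 * o1$life_expectancy, tolerance = 1e-12)
  expect_equal(o2$screen_pos_le25, o1$screen_pos_le25)
  expect_equal(o2$ptb_le34, o1$ptb_le34)
  expect_equal(o2$costs[["ultrasound"]], o1$costs[["ultrasound"]])
})

test_that("null treatment effects with free screening collapse the strategies", {
  p <- zero_screening_costs(null_effect_params(base_params()))
  outs <- lapply(setNames(twincua:::STRATEGIES, twincua:::STRATEGIES),
                 evaluate_strategy, params = p)
  v0 <- twincua:::outcome_vector(outs$no_screen)
  clinical <- setdiff(names(v0), c("screen_pos_le15", "screen_pos_le25"))
  for (s in c("one_step", "two_step"))
    expect_equal(twincua:::outcome_vector(outs[[s]])[clinical], v0[clinical],
                 tolerance = 1e-12)
})

test_that("incremental statistics and dominance classes are exact", {
  mk <- function(strategy, cost, qalys)
    structure(list(strategy = strategy, total_cost = cost,
                   total_qalys = qalys), class = "strategy_outcome")
  inc <- compare_strategies(list(mk("no_screen", 46133, 74.9),
                                 mk("one_step", 46133 - 1262, 74.9 + 0.32),
                                 mk("two_step", 46133 - 2460, 74.9 + 0.62)))
  one <- inc[inc$strategy == "one_step", ]
  expect_equal(one$delta_cost, -1262)
  expect_equal(one$delta_qalys, 0.32)
  expect_equal(one$icer, -1262 / 0.32)          # -3943.75
  expect_equal(one$icer * one$delta_qalys, one$delta_cost, tolerance = 1e-9)
  expect_identical(one$dominance, "dominant")

  # dominated and trade-off classes; undefined ICER at zero QALY delta
  inc2 <- compare_strategies(list(mk("no_screen", 100, 10),
                                  mk("one_step", 150, 9),
                                  mk("two_step", 150, 10)))
  expect_identical(inc2$dominance[inc2$strategy == "one_step"], "dominated")
  two <- inc2[inc2$strategy == "two_step", ]
  expect_true(is.na(two$icer))
  expect_identical(two$dominance, "dominated")  # costs more, same QALYs
  inc3 <- compare_strategies(list(mk("no_screen", 100, 10),
                                  mk("one_step", 150, 11),
                                  mk("two_step", 90, 9)))
  expect_identical(inc3$dominance, c("trade-off", "trade-off"))
  expect_error(compare_strategies(list(mk("one_step", 1, 1),
                                       mk("two_step", 1, 1))),
               "no_screen")
})

test_that("PSA draws are reproducible and share parameters across strategies", {
  p <- base_params()
  psa1 <- run_psa(p, n = 25, seed = 21)
  psa2 <- run_psa(p, n = 25, seed = 21)
  expect_identical(psa1$outcomes, psa2$outcomes)
  expect_identical(psa1$draws, psa2$draws)

  # common random numbers: rebuilding the recorded draw reproduces all three
  # strategies' stored outcomes
  for (i in c(1L, 13L)) {
    ps <- p
    for (nm in names(psa1$draws))
      ps$values <- twincua:::set_path(ps$values, twincua:::split_path(nm),
                                      psa1$draws[i, nm], nm)
    for (s in twincua:::STRATEGIES)
      expect_equal(twincua:::outcome_vector(evaluate_strategy(s, ps)),
                   psa1$outcomes[[s]][i, ], tolerance = 1e-12)
  }

  # summaries bracket their means
  s <- psa1$summary
  expect_true(all(s$lo <= s$mean + 1e-9 & s$mean <= s$hi + 1e-9))
  # ICER consistency for the ratio-of-means convention
  inc <- psa1$incremental
  expect_equal(inc$icer_ratio_of_means * inc$delta_qalys, inc$delta_cost,
               tolerance = 1e-9)
})

test_that("CEAC normalizes, splits ties, and has the right limits", {
  p <- base_params()
  fx <- p
  fx$priors$family <- "fixed"
  psa <- run_psa(fx, n = 3, seed = 2)
  # degenerate PSA: zero-width credible intervals
  expect_true(all(psa$summary$hi - psa$summary$lo == 0))

  cc <- ceac(psa, wtp = c(0, 1e5))
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-12)
  # single deterministic winner: indicator vector
  expect_true(all(cc$probability %in% c(0, 1)))

  # lambda = 0 rewards the cost-minimizing strategy
  base_fit <- twin_cua(p)
  cheapest <- names(which.min(vapply(base_fit$outcomes, `[[`, numeric(1),
                                     "total_cost")))
  cc0 <- ceac(psa, wtp = 0)
  expect_equal(cc0$probability[cc0$strategy == cheapest], 1)

  # exact NMB ties split equally
  fake <- structure(list(
    outcomes = list(
      no_screen = cbind(total_qalys = 10, total_cost = 100),
      one_step = cbind(total_qalys = 11, total_cost = 100 + 5e4),
      two_step = cbind(total_qalys = 9, total_cost = 900)),
    n = 1L), class = "twin_psa")
  tied <- ceac(fake, wtp = 5e4)  # no_screen and one_step NMB equal
  expect_equal(tied$probability[tied$strategy %in% c("no_screen", "one_step")],
               c(0.5, 0.5))
  expect_equal(tied$probability[tied$strategy == "two_step"], 0)
  # large lambda concentrates on the QALY maximizer
  hi <- ceac(fake, wtp = 1e9)
  expect_equal(hi$probability[hi$strategy == "one_step"], 1)
})
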