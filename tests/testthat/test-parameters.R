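# Parameter model: loading, validation, round-trip, overrides, sampling.

test_that("bundled base-case file loads with the published screening values", {
  p <- load_parameters(twincua_example())
  expect_equal(param_value(p, "screening.p_s1_le25"), 0.044)
  expect_equal(param_value(p, "screening.p_s1_le15_given_le25"), 0.468)
  expect_equal(param_value(p, "screening.p_s2_le25_given_s1_neg"), 0.076)
  expect_equal(param_value(p, "screening.p_s2_le15_given_le25_s1neg"), 0.377)
  pr <- p$priors
  i <- match("screening.p_s1_le25", pr$name)
  expect_equal(pr$family[i], "beta")
  expect_equal(c(pr$a[i], pr$b[i]), c(32, 696))
  expect_equal(param_value(p, "rr_progesterone.ga_le28"), 0.53)
  expect_equal(param_value(p, "rr_cerclage.ga_32_34"), 0.30)
})

test_that("write/load round-trips every field within 1e-12", {
  p <- base_params()
  d <- withr::local_tempdir()
  f <- file.path(d, "params.yaml")
  write_parameters(p, f)
  p2 <- load_parameters(f)
  expect_equal(p2$values, p$values, tolerance = 1e-12)
  expect_equal(p2$priors$a, p$priors$a, tolerance = 1e-12)
  expect_identical(p2$priors$name, p$priors$name)
})

test_that("validation rejects out-of-range and degenerate inputs by name", {
  p <- base_params()
  d <- withr::local_tempdir()
  f <- file.path(d, "params.yaml")

  bad <- p
  bad$values$screening$p_s1_le25 <- 1.2
  write_parameters(structure(bad, class = "twin_params"), f)
  expect_error(load_parameters(f), "screening.p_s1_le25")

  bad <- p
  bad$priors$b[bad$priors$name == "rr_progesterone.ga_le28"] <- 0
  write_parameters(structure(bad, class = "twin_params"), f)
  expect_error(load_parameters(f), "rr_progesterone.ga_le28")

  bad <- p
  bad$values$baseline_birth_timing["cl_le15", "ga_le28"] <- 0.5
  write_parameters(structure(bad, class = "twin_params"), f)
  expect_error(load_parameters(f), "baseline_birth_timing.*sum to 1")

  expect_error(load_parameters(file.path(d, "absent.yaml")), "not found")
})

test_that("override changes exactly one value and leaves the input untouched", {
  p <- base_params()
  p2 <- override_parameter(p, "rr_cerclage.ga_le28", 1.17)
  expect_equal(param_value(p2, "rr_cerclage.ga_le28"), 1.17)
  expect_equal(param_value(p, "rr_cerclage.ga_le28"), 0.56)
  a <- flatten_values(p$values)
  b <- flatten_values(p2$values)
  changed <- names(a)[a != b]
  expect_identical(changed, "rr_cerclage.ga_le28")

  same <- override_parameter(p, "discount_rate", 0.015)
  expect_identical(same$values, p$values)

  expect_error(override_parameter(p, "rr_cerclage.ga_le99", 1), "unknown parameter")
  expect_error(override_parameter(p, "no_such.thing", 1), "unknown parameter")
  expect_error(override_parameter(p, "stillbirth_prob.ga_le28", -0.1),
               "outside its mathematical support")
  expect_error(override_parameter(p, "twin_multiplier", 2.5),
               "outside its mathematical support")
})

test_that("all-fixed parameter sets sample to themselves; seeds reproduce", {
  p <- base_params()
  fx <- p
  fx$priors$family <- "fixed"
  expect_identical(sample_parameters(fx, seed = 4)$values, fx$values)

  s1 <- sample_parameters(p, seed = 11)
  s2 <- sample_parameters(p, seed = 11)
  expect_identical(s1$values, s2$values)
  s3 <- sample_parameters(p, seed = 12)
  expect_false(identical(s1$values, s3$values))
})

test_that("sampled values respect their supports and analytic means", {
  p <- base_params()
  n <- 10000L
  set.seed(42)
  draws <- replicate(n, {
    s <- sample_parameters(p)
    c(beta = param_value(s, "screening.p_s1_le25"),
      lnorm = param_value(s, "rr_cerclage.ga_le28"),
      gamma = param_value(s, "costs.cerclage_procedure"),
      bt1 = param_value(s, "baseline_birth_timing.cl_le15.ga_le28"))
  })
  expect_true(all(draws["beta", ] > 0 & draws["beta", ] < 1))
  expect_true(all(draws["lnorm", ] > 0))
  expect_true(all(draws["gamma", ] > 0))

  # beta(32, 696): empirical mean within 3 Monte-Carlo SE of 32/728
  mu <- 32 / 728
  sd_beta <- sqrt(32 * 696 / ((728)^2 * 729))
  expect_lt(abs(mean(draws["beta", ]) - mu), 3 * sd_beta / sqrt(n))

  # lognormal(log 0.56, 0.39): mean within 3 MC SE of exp(mu + s^2/2)
  m_ln <- exp(log(0.56) + 0.39^2 / 2)
  sd_ln <- sqrt((exp(0.39^2) - 1) * exp(2 * log(0.56) + 0.39^2))
  expect_lt(abs(mean(draws["lnorm", ]) - m_ln), 3 * sd_ln / sqrt(n))

  # gamma(shape, rate) with mean 3590, cv 0.25
  expect_lt(abs(mean(draws["gamma", ]) - 3590), 3 * 3590 * 0.25 / sqrt(n))

  # dirichlet rows stay on the simplex with mean ~ concentration share
  s <- sample_parameters(p, seed = 5)
  expect_equal(rowSums(s$values$baseline_birth_timing), rep(1, 3),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(abs(mean(draws["bt1", ]) - 0.30), 3 * sd(draws["bt1", ]) / sqrt(n))
})
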