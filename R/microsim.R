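## Per-individual microsimulation oracle. Simulates pregnancies one at a
## time through the same decision tree and annual mortality process as the
## cohort pipeline; its means must agree with evaluate_strategy() within
## Monte-Carlo error, which is the package's main end-to-end verification.

#' Microsimulation oracle for a screening strategy
#'
#' Simulates \code{n} pregnancies: screening cell (true stratum, detection,
#' detecting screen), treatment uptake, GA category at birth from the
#' cell-specific adjusted distribution, stillbirth, Cesarean section and NICU
#' admission, then one child's lifetime by annual Bernoulli survival draws
#' from the GA-specific mortality schedule with per-cycle discounted utility
#' and cost accrual (the pregnancy total scales the child by the twin
#' multiplier, twins being assumed concordant). Returns the mean and
#' Monte-Carlo standard error of every \code{strategy_outcome} field.
#'
#' @inheritParams stratum_mix
#' @param n number of simulated pregnancies.
#' @param seed integer RNG seed.
#' @return an object of class \code{microsim}: list with \code{estimate} and
#'   \code{se} (named numerics over the outcome fields), \code{n} and
#'   \code{strategy}.
#' @export
microsim_oracle <- function(strategy, params, n = 10000L, seed = 1L) {
  strategy <- match.arg(strategy, STRATEGIES)
  stopifnot(inherits(params, "twin_params"), n >= 1L)
  set.seed(as.integer(seed))
  v <- params$values
  mix <- stratum_mix(strategy, params)
  mix <- mix[mix$prob > 0, , drop = FALSE]
  uptake <- v$treatment_uptake
  tm <- v$twin_multiplier
  op <- v$options

  cell <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$prob)
  detected <- mix$detected[cell]
  treated <- detected & (stats::runif(n) < uptake)

  ## GA category: baseline for untreated, RR-adjusted for treated, by cell.
  ga <- integer(n)
  for (ci in seq_len(nrow(mix))) {
    for (tr in c(FALSE, TRUE)) {
      idx <- which(cell == ci & treated == tr)
      if (!length(idx)) next
      dist <- adjusted_birth_timing(
        v$baseline_birth_timing[mix$stratum[ci], ],
        if (tr) rr_for_treatment(mix$treatment[ci], params) else NULL,
        uptake = 1)
      ga[idx] <- sample.int(5L, length(idx), replace = TRUE, prob = dist)
    }
  }

  stillbirth <- stats::runif(n) < as.numeric(v$stillbirth_prob)[ga]
  cesarean <- stats::runif(n) < v$cesarean_rate
  nicu_adm <- stats::runif(n) < as.numeric(v$nicu_admission)[ga]

  mid <- as.numeric(op$ga_midpoint)
  start_wk <- ifelse(is.na(mix$screen[cell]), NA_real_,
                     op$prog_start_week[paste0("s", mix$screen[cell])])
  prog_weeks <- ifelse(treated,
                       pmax(0, pmin(op$prog_end_week, mid[ga]) - start_wk), 0)

  cost_ultrasound <- rep(v$n_scans[[strategy]] * v$costs$ultrasound_per_scan, n)
  cost_progesterone <- prog_weeks * v$costs$progesterone_per_week
  cost_cerclage <- ifelse(treated & mix$stratum[cell] == "cl_le15",
                          v$costs$cerclage_procedure, 0)
  cost_birth <- ifelse(cesarean, v$costs$cesarean_birth, v$costs$vaginal_birth)
  cost_nicu <- tm * ifelse(nicu_adm,
                           as.numeric(v$costs$nicu_per_admission)[ga], 0)
  pregnancy_cost <- cost_ultrasound + cost_progesterone + cost_cerclage +
    cost_birth + cost_nicu

  ## Child lifetime: annual Bernoulli survival; `lived` counts reward cycles
  ## (alive at cycle start), 1..101 over ages 0-100.
  disc <- (1 + v$discount_rate)^(-AGES)
  lived <- integer(n)
  qalys_child <- numeric(n)
  cost_child <- numeric(n)
  for (g in 1:5) {
    idx <- which(ga == g)
    if (!length(idx)) next
    q <- mortality_schedule(GA_LEVELS[g], params)
    alive <- rep(TRUE, length(idx))
    cycles <- integer(length(idx))
    for (a in 0:99) {
      aw <- which(alive)
      if (!length(aw)) break
      cycles[aw] <- cycles[aw] + 1L           # reward for age a
      dies <- aw[stats::runif(length(aw)) < q[a + 1L]]
      if (length(dies)) alive[dies] <- FALSE
    }
    cycles[alive] <- cycles[alive] + 1L       # age-100 reward for survivors
    u <- v$utility[, GA_LEVELS[g]]
    cvec <- c(v$annual_cost[, GA_LEVELS[g]], rep(v$annual_cost_after9,
                                                 MAX_AGE - 9L))
    cum_u <- cumsum(u * disc)
    cum_c <- cumsum(cvec * disc)
    lived[idx] <- cycles
    qalys_child[idx] <- cum_u[cycles]
    cost_child[idx] <- cum_c[cycles]
  }
  if (isTRUE(op$stillbirth_reduces_cohort)) {
    lived[stillbirth] <- 0L
    qalys_child[stillbirth] <- 0
    cost_child[stillbirth] <- 0
  }

  per <- cbind(
    screen_pos_le15 = as.numeric(detected & mix$stratum[cell] == "cl_le15"),
    screen_pos_le25 = as.numeric(detected),
    ptb_le28 = as.numeric(ga == 1L),
    ptb_le32 = as.numeric(ga <= 2L),
    ptb_le34 = as.numeric(ga <= 3L),
    ptb_lt37 = as.numeric(ga <= 4L),
    stillbirths_per_1000 = 1000 * as.numeric(stillbirth),
    life_expectancy = tm * lived,
    cost_ultrasound = cost_ultrasound,
    cost_progesterone = cost_progesterone,
    cost_cerclage = cost_cerclage,
    cost_birth = cost_birth,
    cost_nicu = cost_nicu,
    pregnancy_cost = pregnancy_cost,
    lifetime_cost = tm * cost_child,
    total_cost = pregnancy_cost + tm * cost_child,
    total_qalys = tm * qalys_child)

  est <- colMeans(per)
  se <- apply(per, 2L, stats::sd) / sqrt(n)
  structure(list(estimate = est, se = se, n = as.integer(n),
                 strategy = strategy), class = "microsim")
}

#' @export
print.microsim <- function(x, ...) {
  cat(sprintf("Microsimulation oracle: %s, n = %d pregnancies\n",
              STRATEGY_LABELS[match(x$strategy, STRATEGIES)], x$n))
  df <- data.frame(outcome = names(x$estimate),
                   estimate = signif(x$estimate, 6),
                   mc_se = signif(x$se, 3), row.names = NULL)
  print(df, row.names = FALSE)
  invisible(x)
}
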