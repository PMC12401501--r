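## Decision tree: screening -> detection -> treatment -> GA at birth.
##
## Latent-stratum model: every pregnancy has a true CL stratum (shortest CL
## over the screening window; CL is assumed never to increase, so the
## two-step detection totals define the stratum prevalences). A strategy
## detects part of the short-CL population -- one-step only what is short at
## 18-20 weeks, two-step additionally what has shortened by 20-22 weeks --
## and detected patients are offered treatment: progesterone for CL <= 25 mm,
## cerclage + progesterone (modelled with the cerclage relative risks) for
## CL <= 15 mm. Undetected short-CL pregnancies keep their true stratum's
## baseline birth timing untreated.

#' Screening cell table for a strategy
#'
#' Decomposes the pregnancy population into cells of (true CL stratum,
#' detected or not, detecting screen, assigned treatment) with their
#' probabilities. The treated-as management marginal (undetected mass
#' counted with the \verb{>25 mm} untreated stratum) is available via
#' \code{\link{stratum_marginal}}; the screen-positive proportions are
#' attached as attributes.
#'
#' @param strategy one of \code{"no_screen"}, \code{"one_step"},
#'   \code{"two_step"}.
#' @param params a \code{twin_params} object.
#' @return a data.frame with columns \code{stratum}, \code{detected},
#'   \code{screen} (1, 2 or NA), \code{treatment} (\code{"none"},
#'   \code{"progesterone"}, \code{"cerclage"}) and \code{prob} (sums to 1),
#'   with attributes \code{screen_pos_le15}, \code{screen_pos_le25} and
#'   \code{prevalence}.
#' @export
stratum_mix <- function(strategy, params) {
  strategy <- match.arg(strategy, STRATEGIES)
  stopifnot(inherits(params, "twin_params"))
  sc <- params$values$screening
  prev <- stratum_prevalence(sc)

  cell <- function(stratum, detected, screen, treatment, prob)
    data.frame(stratum = stratum, detected = detected, screen = screen,
               treatment = treatment, prob = prob, stringsAsFactors = FALSE)

  d15_s1 <- sc$p_s1_le25 * sc$p_s1_le15_given_le25
  d25_s1 <- sc$p_s1_le25 * (1 - sc$p_s1_le15_given_le25)
  d15_s2 <- (1 - sc$p_s1_le25) * sc$p_s2_le25_given_s1_neg *
    sc$p_s2_le15_given_le25_s1neg
  d25_s2 <- (1 - sc$p_s1_le25) * sc$p_s2_le25_given_s1_neg *
    (1 - sc$p_s2_le15_given_le25_s1neg)

  cells <- switch(strategy,
    no_screen = rbind(
      cell("cl_le15", FALSE, NA, "none", prev[["cl_le15"]]),
      cell("cl_15_25", FALSE, NA, "none", prev[["cl_15_25"]]),
      cell("cl_gt25", FALSE, NA, "none", prev[["cl_gt25"]])),
    one_step = rbind(
      cell("cl_le15", TRUE, 1L, "cerclage", d15_s1),
      cell("cl_15_25", TRUE, 1L, "progesterone", d25_s1),
      cell("cl_le15", FALSE, NA, "none", prev[["cl_le15"]] - d15_s1),
      cell("cl_15_25", FALSE, NA, "none", prev[["cl_15_25"]] - d25_s1),
      cell("cl_gt25", FALSE, NA, "none", prev[["cl_gt25"]])),
    two_step = rbind(
      cell("cl_le15", TRUE, 1L, "cerclage", d15_s1),
      cell("cl_le15", TRUE, 2L, "cerclage", d15_s2),
      cell("cl_15_25", TRUE, 1L, "progesterone", d25_s1),
      cell("cl_15_25", TRUE, 2L, "progesterone", d25_s2),
      cell("cl_gt25", FALSE, NA, "none", prev[["cl_gt25"]])))
  if (any(cells$prob < -1e-12))
    stop("screening probabilities imply a negative cell mass", call. = FALSE)
  cells$prob <- pmax(cells$prob, 0)

  attr(cells, "screen_pos_le15") <-
    sum(cells$prob[cells$detected & cells$stratum == "cl_le15"])
  attr(cells, "screen_pos_le25") <- sum(cells$prob[cells$detected])
  attr(cells, "prevalence") <- prev
  attr(cells, "strategy") <- strategy
  cells
}

#' Treated-as stratum marginal of a screening cell table
#'
#' Collapses a \code{\link{stratum_mix}} table to the three management
#' strata: detected \verb{<=15 mm}, detected \verb{15-25 mm}, and everything
#' managed expectantly (including undetected short CL). Under no screening
#' all mass is managed expectantly.
#'
#' @param mix a cell table from \code{\link{stratum_mix}}.
#' @return named numeric of length 3 summing to 1.
#' @export
stratum_marginal <- function(mix) {
  out <- c(cl_le15 = sum(mix$prob[mix$detected & mix$stratum == "cl_le15"]),
           cl_15_25 = sum(mix$prob[mix$detected & mix$stratum == "cl_15_25"]),
           cl_gt25 = sum(mix$prob[!mix$detected]))
  out
}

#' Apply a treatment relative risk to a birth-timing distribution
#'
#' Each preterm category's probability is multiplied by
#' \code{uptake * rr + (1 - uptake)}; the term (\verb{>37} weeks) category
#' receives the residual mass so the distribution sums to 1. With
#' \code{rr = NULL} or all relative risks equal to 1 and a baseline summing
#' to 1, the baseline is returned unchanged (up to the residual convention).
#'
#' @param baseline named numeric of length 5 over the GA categories.
#' @param rr named numeric of length 4 (preterm categories) of relative
#'   risks, or \code{NULL} for no treatment.
#' @param uptake probability that a detected patient takes up treatment.
#' @return named numeric of length 5 summing to 1.
#' @export
adjusted_birth_timing <- function(baseline, rr = NULL, uptake = 1) {
  stopifnot(length(baseline) == 5L, uptake >= 0, uptake <= 1)
  eff <- if (is.null(rr)) rep(1, 4L) else {
    stopifnot(length(rr) == 4L, all(rr > 0))
    uptake * as.numeric(rr) + (1 - uptake)
  }
  pre <- as.numeric(baseline[1:4]) * eff
  term <- 1 - sum(pre)
  if (term < -1e-12)
    stop("adjusted preterm birth probabilities exceed 1 ",
         "(preterm mass ", format(sum(pre), digits = 6),
         "); inconsistent baseline/relative-risk inputs", call. = FALSE)
  stats::setNames(c(pre, max(term, 0)), GA_LEVELS)
}

rr_for_treatment <- function(treatment, params) {
  switch(treatment,
    none = NULL,
    progesterone = params$values$rr_progesterone,
    cerclage = params$values$rr_cerclage,
    stop("unknown treatment: ", treatment, call. = FALSE))
}

#' GA-at-birth distribution under a screening strategy
#'
#' Mixture over the \code{\link{stratum_mix}} cells of
#' \code{\link{adjusted_birth_timing}} applied to each cell's true-stratum
#' baseline: detected \verb{<=15 mm} cells receive the cerclage relative
#' risks (cerclage + progesterone is conservatively taken as cerclage alone),
#' detected \verb{15-25 mm} cells the progesterone relative risks, all other
#' mass is untreated.
#'
#' @inheritParams stratum_mix
#' @return named numeric of length 5 summing to 1.
#' @export
strategy_birth_timing <- function(strategy, params) {
  mix <- stratum_mix(strategy, params)
  bt <- params$values$baseline_birth_timing
  uptake <- params$values$treatment_uptake
  out <- numeric(5L)
  for (i in seq_len(nrow(mix))) {
    if (mix$prob[i] == 0) next
    adj <- adjusted_birth_timing(bt[mix$stratum[i], ],
                                 rr_for_treatment(mix$treatment[i], params),
                                 uptake = if (mix$detected[i]) uptake else 1)
    out <- out + mix$prob[i] * adj
  }
  stats::setNames(out, GA_LEVELS)
}

#' Stillbirth rate per 1000 pregnancies under a strategy
#'
#' Expected stillbirths per 1000 pregnancies: the GA-at-birth distribution
#' dotted with the GA-specific stillbirth probabilities. Reported as a
#' clinical outcome; by default stillbirth does not remove mass from the
#' lifetime cohort model (see \code{options.stillbirth_reduces_cohort}).
#'
#' @inheritParams stratum_mix
#' @param birth_timing optional GA distribution to use instead of
#'   \code{\link{strategy_birth_timing}} (length 5, sums to 1).
#' @return rate per 1000 pregnancies.
#' @export
stillbirth_rate <- function(strategy, params, birth_timing = NULL) {
  bt <- birth_timing %||% strategy_birth_timing(strategy, params)
  stopifnot(length(bt) == 5L)
  1000 * sum(as.numeric(bt) * as.numeric(params$values$stillbirth_prob))
}

## Expected weeks of progesterone for a treated patient in one detection
## cell: from the detecting screen's start week to 36 weeks or birth
## (GA-category midpoint), whichever comes sooner.
expected_prog_weeks <- function(stratum, screen, params) {
  op <- params$values$options
  start <- op$prog_start_week[[paste0("s", screen)]]
  dist <- adjusted_birth_timing(params$values$baseline_birth_timing[stratum, ],
                                rr_for_treatment(
                                  if (stratum == "cl_le15") "cerclage"
                                  else "progesterone", params),
                                uptake = 1)
  weeks <- pmax(0, pmin(op$prog_end_week, op$ga_midpoint) - start)
  sum(dist * weeks)
}

#' Pregnancy-phase costs of a strategy
#'
#' Per-pregnancy expected costs (2023 CAD): screening ultrasounds
#' (\code{n_scans} per strategy times the per-scan cost), progesterone
#' (expected treated weeks times the weekly cost, over detected cells, times
#' uptake), cerclage (procedure cost times the \verb{<=15 mm} detection
#' probability times uptake), birth (Cesarean-rate-weighted mix of Cesarean
#' and vaginal birth), and NICU admission (admission probability times cost
#' per admission by GA category, doubled by the twin multiplier).
#'
#' @inheritParams stratum_mix
#' @return named numeric with components \code{ultrasound},
#'   \code{progesterone}, \code{cerclage}, \code{birth}, \code{nicu},
#'   \code{total}.
#' @export
pregnancy_costs <- function(strategy, params) {
  strategy <- match.arg(strategy, STRATEGIES)
  v <- params$values
  mix <- stratum_mix(strategy, params)
  bt <- strategy_birth_timing(strategy, params)
  uptake <- v$treatment_uptake

  ultrasound <- v$n_scans[[strategy]] * v$costs$ultrasound_per_scan

  det <- mix[mix$detected & mix$prob > 0, , drop = FALSE]
  prog_weeks <- 0
  if (nrow(det))
    prog_weeks <- sum(vapply(seq_len(nrow(det)), function(i)
      det$prob[i] * expected_prog_weeks(det$stratum[i], det$screen[i], params),
      numeric(1L)))
  progesterone <- uptake * prog_weeks * v$costs$progesterone_per_week

  cerclage <- uptake * attr(mix, "screen_pos_le15") * v$costs$cerclage_procedure

  birth <- v$cesarean_rate * v$costs$cesarean_birth +
    (1 - v$cesarean_rate) * v$costs$vaginal_birth

  nicu <- v$twin_multiplier *
    sum(as.numeric(bt) * as.numeric(v$nicu_admission) *
          as.numeric(v$costs$nicu_per_admission))

  out <- c(ultrasound = ultrasound, progesterone = progesterone,
           cerclage = cerclage, birth = birth, nicu = nicu)
  c(out, total = sum(out))
}
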