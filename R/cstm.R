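## Lifetime cohort state transition model: two states (alive, dead), 1-year
## cycles over integer ages 0-100 inclusive (101 cycles), run separately for
## each GA-at-birth category and weighted by the decision tree's birth-timing
## distribution.

#' Annual mortality schedule for a GA category
#'
#' Ages 0-45: the term (lifetable) annual death probability is scaled on the
#' hazard scale by the GA- and age-specific hazard ratio,
#' \code{q(a) = 1 - (1 - q_term(a))^HR(ga, a)}. From age 46 onwards (and for
#' the term category at all ages) the hazard of death is the same across GA
#' categories, so the lifetable applies directly.
#'
#' @param ga GA category, one of \code{"ga_le28"}, \code{"ga_28_32"},
#'   \code{"ga_32_34"}, \code{"ga_34_37"}, \code{"ga_gt37"}.
#' @param params a \code{twin_params} object.
#' @return named numeric of annual death probabilities for ages 0-99.
#' @export
mortality_schedule <- function(ga, params) {
  ga <- match.arg(ga, GA_LEVELS)
  q <- params$values$lifetable
  hr <- params$values$hazard_ratio[, ga]
  if (any(hr <= 0)) stop("hazard ratios must be > 0", call. = FALSE)
  young <- 1:46  # ages 0-45
  q[young] <- 1 - (1 - q[young])^hr
  q
}

#' Blend utilities by neurosensory-impairment proportion
#'
#' Linear blend \code{nsi_prop * u_nsi + (1 - nsi_prop) * u_no_nsi} used to
#' build GA-category utility trajectories from the impaired and unimpaired
#' HUI3 trajectories.
#'
#' @param u_nsi,u_no_nsi utilities (scalars or equal-length vectors) in the
#'   HUI3 range \eqn{[-0.36, 1]}.
#' @param nsi_prop proportion with neurosensory impairment, in \eqn{[0, 1]}.
#' @return blended utility, same length as the inputs.
#' @export
blend_utility <- function(u_nsi, u_no_nsi, nsi_prop) {
  stopifnot(length(nsi_prop) == 1L, nsi_prop >= 0, nsi_prop <= 1,
            all(u_nsi >= UTILITY_MIN & u_nsi <= 1),
            all(u_no_nsi >= UTILITY_MIN & u_no_nsi <= 1))
  nsi_prop * u_nsi + (1 - nsi_prop) * u_no_nsi
}

#' Run the lifetime cohort model for one GA category
#'
#' Starts a cohort of size 1 at age 0 and applies the GA-specific mortality
#' schedule: \code{S(0) = 1}, \code{S(a+1) = S(a) * (1 - q(a))}. Rewards
#' accrue for every cycle the cohort is alive at its start (ages 0-100; no
#' half-cycle correction unless \code{options.half_cycle} is set, in which
#' case half of each cycle's deaths are removed from that cycle's reward
#' mass). Year-0 rewards are undiscounted; year \code{a} is discounted by
#' \code{(1 + r)^-a}. Annual costs follow the ages 0-9 table and are constant
#' (\code{annual_cost_after9}) from age 10 onwards.
#'
#' @inheritParams mortality_schedule
#' @return an object of class \code{cstm_result}: a list with
#'   \code{discounted_qalys}, \code{discounted_cost} (2023 CAD),
#'   \code{life_expectancy} (undiscounted years, the sum of the survival
#'   curve over the 101 cycles) and \code{survival_curve} (probability alive
#'   at the start of each age 0-100).
#' @export
run_cstm <- function(ga, params) {
  ga <- match.arg(ga, GA_LEVELS)
  v <- params$values
  q <- mortality_schedule(ga, params)

  S <- c(1, cumprod(1 - q))          # ages 0..100
  names(S) <- age_names(AGES)

  u <- v$utility[, ga]
  cost <- c(v$annual_cost[, ga], rep(v$annual_cost_after9, MAX_AGE - 9L))
  if (length(u) != length(AGES) || length(cost) != length(AGES))
    stop("utility/cost trajectories must cover ages 0-100", call. = FALSE)

  w <- S
  if (isTRUE(v$options$half_cycle)) {
    deaths <- c(S[-length(S)] - S[-1L], 0)
    w <- S - deaths / 2
  }
  disc <- (1 + v$discount_rate)^(-AGES)

  structure(list(
    ga = ga,
    discounted_qalys = sum(w * u * disc),
    discounted_cost = sum(w * cost * disc),
    life_expectancy = sum(S),
    survival_curve = S), class = "cstm_result")
}

#' @export
print.cstm_result <- function(x, ...) {
  cat(sprintf("Cohort model result (%s): %.2f discounted QALYs, $%s discounted cost, %.1f y life expectancy\n",
              GA_LABELS[match(x$ga, GA_LEVELS)], x$discounted_qalys,
              format(round(x$discounted_cost), big.mark = ","),
              x$life_expectancy))
  invisible(x)
}
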