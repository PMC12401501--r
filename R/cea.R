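## Strategy evaluation and incremental cost-utility statistics.

OUTCOME_FIELDS <- c("screen_pos_le15", "screen_pos_le25",
                    "ptb_le28", "ptb_le32", "ptb_le34", "ptb_lt37",
                    "stillbirths_per_1000", "life_expectancy",
                    "cost_ultrasound", "cost_progesterone", "cost_cerclage",
                    "cost_birth", "cost_nicu", "pregnancy_cost",
                    "lifetime_cost", "total_cost", "total_qalys")

#' Evaluate one screening strategy
#'
#' Runs the decision tree, then the lifetime cohort model for each GA
#' category, and aggregates: per-pregnancy lifetime outcomes are the
#' birth-timing-weighted sums of the per-child cohort results scaled by the
#' twin multiplier (each pregnancy is assumed to yield
#' \code{twin_multiplier} concordant neonates). Preterm-birth proportions are
#' cumulative sums of the preterm categories. If
#' \code{options.stillbirth_reduces_cohort} is set, each GA category's cohort
#' entry mass is reduced by its stillbirth probability; by default stillbirth
#' is reported as a clinical outcome only.
#'
#' @inheritParams stratum_mix
#' @return an object of class \code{strategy_outcome}: a list with the
#'   screen-positive proportions, PTB proportions, stillbirths per 1000
#'   pregnancies, per-pregnancy life expectancy, the pregnancy cost
#'   components, discounted lifetime cost, total cost, total QALYs, and the
#'   underlying \code{birth_timing} distribution.
#' @export
evaluate_strategy <- function(strategy, params) {
  strategy <- match.arg(strategy, STRATEGIES)
  v <- params$values
  mix <- stratum_mix(strategy, params)
  bt <- strategy_birth_timing(strategy, params)
  pc <- pregnancy_costs(strategy, params)

  cstm <- lapply(stats::setNames(GA_LEVELS, GA_LEVELS), run_cstm,
                 params = params)
  qal <- vapply(cstm, `[[`, numeric(1L), "discounted_qalys")
  lcost <- vapply(cstm, `[[`, numeric(1L), "discounted_cost")
  le <- vapply(cstm, `[[`, numeric(1L), "life_expectancy")

  entry <- as.numeric(bt)
  if (isTRUE(v$options$stillbirth_reduces_cohort))
    entry <- entry * (1 - as.numeric(v$stillbirth_prob))
  tm <- v$twin_multiplier

  structure(list(
    strategy = strategy,
    screen_pos_le15 = attr(mix, "screen_pos_le15"),
    screen_pos_le25 = attr(mix, "screen_pos_le25"),
    ptb_le28 = unname(bt[1L]),
    ptb_le32 = unname(bt[1L] + bt[2L]),
    ptb_le34 = unname(sum(bt[1:3])),
    ptb_lt37 = unname(sum(bt[1:4])),
    stillbirths_per_1000 = stillbirth_rate(strategy, params, birth_timing = bt),
    life_expectancy = tm * sum(entry * le),
    costs = pc,
    lifetime_cost = tm * sum(entry * lcost),
    total_cost = unname(pc[["total"]]) + tm * sum(entry * lcost),
    total_qalys = tm * sum(entry * qal),
    birth_timing = bt), class = "strategy_outcome")
}

## Flatten a strategy_outcome to the named numeric consumed by PSA/reports.
outcome_vector <- function(out) {
  c(screen_pos_le15 = out$screen_pos_le15,
    screen_pos_le25 = out$screen_pos_le25,
    ptb_le28 = out$ptb_le28, ptb_le32 = out$ptb_le32,
    ptb_le34 = out$ptb_le34, ptb_lt37 = out$ptb_lt37,
    stillbirths_per_1000 = out$stillbirths_per_1000,
    life_expectancy = out$life_expectancy,
    cost_ultrasound = unname(out$costs[["ultrasound"]]),
    cost_progesterone = unname(out$costs[["progesterone"]]),
    cost_cerclage = unname(out$costs[["cerclage"]]),
    cost_birth = unname(out$costs[["birth"]]),
    cost_nicu = unname(out$costs[["nicu"]]),
    pregnancy_cost = unname(out$costs[["total"]]),
    lifetime_cost = out$lifetime_cost,
    total_cost = out$total_cost,
    total_qalys = out$total_qalys)
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(STRATEGY_LABELS[match(x$strategy, STRATEGIES)], "\n")
  cat(sprintf("  screen positive: %.3f (<=25 mm), %.3f (<=15 mm)\n",
              x$screen_pos_le25, x$screen_pos_le15))
  cat(sprintf("  PTB: %.3f (<=28 wk), %.3f (<=32 wk), %.3f (<=34 wk), %.3f (<37 wk)\n",
              x$ptb_le28, x$ptb_le32, x$ptb_le34, x$ptb_lt37))
  cat(sprintf("  stillbirths/1000: %.2f; life expectancy: %.2f y/pregnancy\n",
              x$stillbirths_per_1000, x$life_expectancy))
  cat(sprintf("  total cost: $%s; total QALYs: %.2f (per pregnancy)\n",
              format(round(x$total_cost), big.mark = ","), x$total_qalys))
  invisible(x)
}

#' Incremental cost-effectiveness versus no screening
#'
#' Computes, for each screening strategy, the cost and QALY deltas versus the
#' no-screening comparator, the ICER (\code{delta_cost / delta_qalys}, left
#' \code{NA} when the QALY delta is zero within tolerance) and the dominance
#' class: \code{dominant} (cheaper and at least as effective, one strictly),
#' \code{dominated} (the reverse) or \code{trade-off}. Ties within 1e-9 are
#' classed as trade-offs.
#'
#' @param outcomes list of three \code{strategy_outcome} objects (in any
#'   order) containing the \code{no_screen} comparator.
#' @return data.frame with one row per non-comparator strategy: columns
#'   \code{strategy}, \code{comparator}, \code{delta_cost},
#'   \code{delta_qalys}, \code{icer}, \code{dominance}.
#' @export
compare_strategies <- function(outcomes) {
  nm <- vapply(outcomes, `[[`, character(1L), "strategy")
  names(outcomes) <- nm
  if (!("no_screen" %in% nm))
    stop("comparator 'no_screen' missing from outcomes", call. = FALSE)
  ref <- outcomes$no_screen
  others <- setdiff(intersect(STRATEGIES, nm), "no_screen")
  tol <- 1e-9
  rows <- lapply(others, function(s) {
    dc <- outcomes[[s]]$total_cost - ref$total_cost
    dq <- outcomes[[s]]$total_qalys - ref$total_qalys
    icer <- if (abs(dq) > tol) dc / dq else NA_real_
    dominance <-
      if (dc <= tol && dq >= -tol && (dc < -tol || dq > tol)) "dominant"
      else if (dc >= -tol && dq <= tol && (dc > tol || dq < -tol)) "dominated"
      else "trade-off"
    data.frame(strategy = s, comparator = "no_screen", delta_cost = dc,
               delta_qalys = dq, icer = icer, dominance = dominance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full cost-utility analysis at one parameter set
#'
#' Evaluates all three screening strategies and the incremental statistics
#' versus no screening at the given (base-case or sampled) parameter values.
#'
#' @param params a \code{twin_params} object, e.g. from
#'   \code{\link{base_case_parameters}} or \code{\link{load_parameters}}.
#' @return an object of class \code{twin_cua}: a list with \code{outcomes}
#'   (named list of \code{strategy_outcome}), \code{incremental} (the
#'   \code{\link{compare_strategies}} table) and \code{params}.
#' @examples
#' fit <- twin_cua(base_case_parameters())
#' fit
#' as.data.frame(fit)
#' @export
twin_cua <- function(params) {
  stopifnot(inherits(params, "twin_params"))
  outcomes <- lapply(stats::setNames(STRATEGIES, STRATEGIES),
                     evaluate_strategy, params = params)
  structure(list(outcomes = outcomes,
                 incremental = compare_strategies(outcomes),
                 params = params), class = "twin_cua")
}

#' @export
as.data.frame.twin_cua <- function(x, ...) {
  m <- vapply(x$outcomes, outcome_vector, numeric(length(OUTCOME_FIELDS)))
  data.frame(outcome = rownames(m), m, row.names = NULL,
             check.names = FALSE)
}

#' @export
print.twin_cua <- function(x, ...) {
  cat("Cost-utility analysis of CL screening in twin pregnancy (base case)\n\n")
  df <- as.data.frame(x)
  money <- grepl("cost", df$outcome)
  shown <- df
  shown[money, -1] <- round(shown[money, -1])
  shown[!money, -1] <- round(shown[!money, -1], 3)
  print(shown, row.names = FALSE)
  cat("\nIncremental versus no screening:\n")
  inc <- x$incremental
  inc$delta_cost <- round(inc$delta_cost)
  inc$delta_qalys <- round(inc$delta_qalys, 3)
  inc$icer <- round(inc$icer)
  print(inc, row.names = FALSE)
  invisible(x)
}

#' @export
summary.twin_cua <- function(object, ...) {
  dom <- object$incremental$strategy[object$incremental$dominance == "dominant"]
  cat("Strategies evaluated:", paste(STRATEGIES, collapse = ", "), "\n")
  if (length(dom))
    cat("Dominant versus no screening:", paste(dom, collapse = ", "), "\n")
  print(object)
  invisible(object)
}
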