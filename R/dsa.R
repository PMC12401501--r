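## Deterministic sensitivity analysis: one- and two-way parameter sweeps with
## bisection-located thresholds where the preferred strategy switches.

DSA_CRITERIA <- c("net_benefit", "total_cost", "total_qalys",
                  "ptb_le28", "ptb_le34")

## Score each strategy at one parameter set; the winner maximizes the score.
dsa_scores <- function(params, criterion, lambda) {
  vapply(STRATEGIES, function(s) {
    out <- evaluate_strategy(s, params)
    switch(criterion,
      net_benefit = lambda * out$total_qalys - out$total_cost,
      total_cost = -out$total_cost,
      total_qalys = out$total_qalys,
      ptb_le28 = -out$ptb_le28,
      ptb_le34 = -out$ptb_le34)
  }, numeric(1L))
}

dsa_winner <- function(params, criterion, lambda)
  STRATEGIES[which.max(dsa_scores(params, criterion, lambda))]

default_grid <- function(params, name, length.out = 11L) {
  pr <- params$priors
  i <- match(name, pr$name)
  if (is.na(i) || !is.finite(pr$low[i]) || !is.finite(pr$high[i]))
    stop("no clinical range recorded for '", name,
         "'; supply an explicit grid", call. = FALSE)
  seq(pr$low[i], pr$high[i], length.out = length.out)
}

## Locate the switch point between grid values lo (winner w_lo) and hi
## (winner w_hi) by bisection to relative tolerance rtol.
bisect_threshold <- function(params, name, lo, hi, w_lo, criterion, lambda,
                             rtol = 1e-6) {
  while (hi - lo > rtol * max(1, abs(hi))) {
    mid <- (lo + hi) / 2
    w <- dsa_winner(override_parameter(params, name, mid), criterion, lambda)
    if (identical(w, w_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' One-way deterministic sensitivity analysis
#'
#' Sweeps one parameter over a grid (defaulting to its clinical range) with
#' all other parameters at their base-case values, records the preferred
#' strategy at each grid point under the chosen criterion, and refines every
#' switch point between adjacent grid values by bisection to a relative
#' tolerance of 1e-6. Criteria: \code{net_benefit} (greatest
#' \eqn{\lambda \cdot QALYs - cost} at willingness-to-pay \code{lambda}),
#' \code{total_cost} (lowest cost), \code{total_qalys} (highest QALYs),
#' \code{ptb_le28} / \code{ptb_le34} (lowest preterm-birth probability).
#'
#' @inheritParams twin_cua
#' @param name dot-path of the parameter to vary (see
#'   \code{\link{param_value}}); the grid may exceed the clinical range but
#'   not the mathematical support.
#' @param grid numeric grid of values; default is 11 points across the
#'   parameter's recorded clinical range.
#' @param criterion decision criterion, see Details.
#' @param lambda willingness-to-pay for \code{net_benefit} (2023 CAD per
#'   QALY; the analysis ceiling of $100,000 by default).
#' @return an object of class \code{twin_dsa}: \code{grid} (data.frame of
#'   \code{value}, \code{winner}), \code{thresholds} (data.frame of located
#'   switch values with the winners on each side), plus the call settings.
#' @export
one_way_dsa <- function(params, name, grid = NULL,
                        criterion = c("net_benefit", "total_cost",
                                      "total_qalys", "ptb_le28", "ptb_le34"),
                        lambda = 1e5) {
  stopifnot(inherits(params, "twin_params"))
  criterion <- match.arg(criterion)
  if (is.null(grid)) grid <- default_grid(params, name)
  grid <- sort(unique(as.numeric(grid)))
  winners <- vapply(grid, function(x)
    dsa_winner(override_parameter(params, name, x), criterion, lambda),
    character(1L))
  th <- list()
  for (i in seq_len(length(grid) - 1L)) {
    if (winners[i] != winners[i + 1L]) {
      t0 <- bisect_threshold(params, name, grid[i], grid[i + 1L], winners[i],
                             criterion, lambda)
      th[[length(th) + 1L]] <- data.frame(
        parameter = name, threshold = t0,
        winner_below = winners[i], winner_above = winners[i + 1L],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    parameter = name, criterion = criterion, lambda = lambda,
    grid = data.frame(value = grid, winner = winners,
                      stringsAsFactors = FALSE),
    thresholds = if (length(th)) do.call(rbind, th) else
      data.frame(parameter = character(), threshold = numeric(),
                 winner_below = character(), winner_above = character(),
                 stringsAsFactors = FALSE)), class = "twin_dsa")
}

#' @export
print.twin_dsa <- function(x, ...) {
  cat(sprintf("One-way DSA of '%s' (criterion: %s%s)\n", x$parameter,
              x$criterion,
              if (x$criterion == "net_benefit")
                sprintf(" at $%s/QALY", format(x$lambda, big.mark = ","))
              else ""))
  print(x$grid, row.names = FALSE)
  if (nrow(x$thresholds)) {
    cat("Thresholds:\n")
    print(x$thresholds, row.names = FALSE)
  } else cat("Preferred strategy constant across the grid\n")
  invisible(x)
}

#' Two-way deterministic sensitivity analysis
#'
#' Sweeps two parameters over a lattice and records the preferred strategy at
#' each point; for each value of the second parameter the switch points along
#' the first parameter's axis are refined by bisection, tracing the decision
#' boundary as per-row thresholds.
#'
#' @inheritParams one_way_dsa
#' @param name_a,name_b dot-paths of the two parameters.
#' @param grid_a,grid_b numeric grids (defaults: 11 points across each
#'   clinical range). A length-1 \code{grid_b} reduces to a one-way analysis
#'   at that value.
#' @return an object of class \code{twin_dsa2}: \code{grid} (long data.frame
#'   of \code{value_a}, \code{value_b}, \code{winner}) and
#'   \code{thresholds} (per \code{value_b} switch points along
#'   \code{name_a}), plus the call settings.
#' @export
two_way_dsa <- function(params, name_a, grid_a = NULL, name_b, grid_b = NULL,
                        criterion = c("net_benefit", "total_cost",
                                      "total_qalys", "ptb_le28", "ptb_le34"),
                        lambda = 1e5) {
  stopifnot(inherits(params, "twin_params"))
  criterion <- match.arg(criterion)
  if (is.null(grid_a)) grid_a <- default_grid(params, name_a)
  if (is.null(grid_b)) grid_b <- default_grid(params, name_b)
  grid_a <- sort(unique(as.numeric(grid_a)))
  grid_b <- sort(unique(as.numeric(grid_b)))
  rows <- list(); th <- list()
  for (b in grid_b) {
    pb <- override_parameter(params, name_b, b)
    one <- one_way_dsa(pb, name_a, grid = grid_a, criterion = criterion,
                       lambda = lambda)
    rows[[length(rows) + 1L]] <- data.frame(
      value_a = one$grid$value, value_b = b, winner = one$grid$winner,
      stringsAsFactors = FALSE)
    if (nrow(one$thresholds))
      th[[length(th) + 1L]] <- data.frame(
        value_b = b, threshold_a = one$thresholds$threshold,
        winner_below = one$thresholds$winner_below,
        winner_above = one$thresholds$winner_above,
        stringsAsFactors = FALSE)
  }
  structure(list(
    parameter_a = name_a, parameter_b = name_b, criterion = criterion,
    lambda = lambda,
    grid = do.call(rbind, rows),
    thresholds = if (length(th)) do.call(rbind, th) else
      data.frame(value_b = numeric(), threshold_a = numeric(),
                 winner_below = character(), winner_above = character(),
                 stringsAsFactors = FALSE)), class = "twin_dsa2")
}

#' @export
print.twin_dsa2 <- function(x, ...) {
  cat(sprintf("Two-way DSA of '%s' x '%s' (criterion: %s)\n", x$parameter_a,
              x$parameter_b, x$criterion))
  tab <- table(x$grid$winner)
  cat("Preferred strategy over the lattice:\n")
  print(tab)
  if (nrow(x$thresholds)) {
    cat("Boundary (thresholds along", x$parameter_a, "per value of",
        x$parameter_b, "):\n")
    print(x$thresholds, row.names = FALSE)
  }
  invisible(x)
}
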