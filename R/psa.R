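## Probabilistic sensitivity analysis and the cost-effectiveness
## acceptability curve.

#' Probabilistic sensitivity analysis
#'
#' Draws \code{n} joint parameter samples with
#' \code{\link{sample_parameters}} and evaluates all three strategies on each
#' draw (common random numbers: within a draw the strategies share the
#' identical sampled parameter set, recorded in \code{$draws}). Posterior
#' summaries are means with 95\% credible intervals (linear-interpolation
#' empirical 2.5/97.5 percentiles). Two ICER conventions are reported for
#' each screening strategy: the ratio of mean deltas, and the mean of
#' per-draw ratios (which is unstable when QALY deltas change sign across
#' draws).
#'
#' @inheritParams twin_cua
#' @param n number of draws (the analysis uses 1000).
#' @param seed integer seed; results are reproducible given the seed.
#' @return an object of class \code{twin_psa}: \code{outcomes} (list of
#'   n-by-field matrices per strategy), \code{draws} (data.frame of sampled
#'   parameter values per draw), \code{summary} (long data.frame of
#'   mean/lo/hi per strategy and outcome), \code{incremental} (per-strategy
#'   deltas with credible intervals and both ICER conventions), \code{n},
#'   \code{seed}.
#' @seealso \code{\link{ceac}}
#' @export
run_psa <- function(params, n = 1000L, seed = 1L) {
  stopifnot(inherits(params, "twin_params"), n >= 1L)
  set.seed(as.integer(seed))
  sampled_names <- params$priors$name[params$priors$family != "fixed"]
  nf <- length(OUTCOME_FIELDS)
  outcomes <- lapply(stats::setNames(STRATEGIES, STRATEGIES), function(s)
    matrix(NA_real_, n, nf, dimnames = list(NULL, OUTCOME_FIELDS)))
  draws <- matrix(NA_real_, n, length(sampled_names),
                  dimnames = list(NULL, sampled_names))
  ## A joint draw can be internally inconsistent (sampled relative risks and
  ## baseline birth timing pushing a stratum's preterm mass above 1); such
  ## draws are rejected and redrawn, truncating the joint distribution to
  ## coherent parameter sets.
  n_rejected <- 0L
  for (i in seq_len(n)) {
    repeat {
      ps <- sample_parameters(params)
      res <- try(lapply(stats::setNames(STRATEGIES, STRATEGIES),
                        evaluate_strategy, params = ps), silent = TRUE)
      if (!inherits(res, "try-error")) break
      n_rejected <- n_rejected + 1L
      if (n_rejected > 100L * n)
        stop("PSA rejection rate implausibly high; check parameter ",
             "distributions", call. = FALSE)
    }
    draws[i, ] <- vapply(sampled_names, function(nm) param_value(ps, nm),
                         numeric(1L))
    for (s in STRATEGIES)
      outcomes[[s]][i, ] <- outcome_vector(res[[s]])
  }

  qlohi <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE,
                                       type = 7)
  summ <- do.call(rbind, lapply(STRATEGIES, function(s) {
    m <- outcomes[[s]]
    data.frame(strategy = s, outcome = colnames(m),
               mean = colMeans(m),
               lo = apply(m, 2L, function(x) qlohi(x)[1L]),
               hi = apply(m, 2L, function(x) qlohi(x)[2L]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  inc <- do.call(rbind, lapply(c("one_step", "two_step"), function(s) {
    dc <- outcomes[[s]][, "total_cost"] - outcomes$no_screen[, "total_cost"]
    dq <- outcomes[[s]][, "total_qalys"] - outcomes$no_screen[, "total_qalys"]
    ratio <- ifelse(abs(dq) > 1e-12, dc / dq, NA_real_)
    data.frame(strategy = s,
               delta_cost = mean(dc), delta_cost_lo = qlohi(dc)[1L],
               delta_cost_hi = qlohi(dc)[2L],
               delta_qalys = mean(dq), delta_qalys_lo = qlohi(dq)[1L],
               delta_qalys_hi = qlohi(dq)[2L],
               icer_ratio_of_means = if (abs(mean(dq)) > 1e-12)
                 mean(dc) / mean(dq) else NA_real_,
               icer_mean_of_ratios = mean(ratio, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))

  structure(list(outcomes = outcomes, draws = as.data.frame(draws),
                 summary = summ, incremental = inc,
                 n = as.integer(n), seed = as.integer(seed),
                 n_rejected = n_rejected),
            class = "twin_psa")
}

#' @export
print.twin_psa <- function(x, digits = 3, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d draws (seed %d%s)\n\n",
              x$n, x$seed,
              if (x$n_rejected > 0)
                sprintf(", %d incoherent draws rejected", x$n_rejected)
              else ""))
  key <- x$summary[x$summary$outcome %in%
                     c("total_cost", "total_qalys", "ptb_le34",
                       "stillbirths_per_1000"), ]
  key[c("mean", "lo", "hi")] <- lapply(key[c("mean", "lo", "hi")], signif,
                                       digits = 6)
  print(key, row.names = FALSE)
  cat("\nIncremental versus no screening (means, 95% CrI):\n")
  inc <- x$incremental
  inc[-1] <- lapply(inc[-1], function(z) round(z, 2))
  print(inc, row.names = FALSE)
  invisible(x)
}

#' @export
summary.twin_psa <- function(object, ...) {
  print(object)
  invisible(object$summary)
}

#' Incremental cost-effectiveness plane
#'
#' Scatter of per-draw incremental QALYs versus incremental costs (versus no
#' screening) for the two screening strategies.
#'
#' @param x a \code{twin_psa} object.
#' @param ... passed to \code{plot}.
#' @export
plot.twin_psa <- function(x, ...) {
  dq <- cbind(one_step = x$outcomes$one_step[, "total_qalys"] -
                x$outcomes$no_screen[, "total_qalys"],
              two_step = x$outcomes$two_step[, "total_qalys"] -
                x$outcomes$no_screen[, "total_qalys"])
  dc <- cbind(one_step = x$outcomes$one_step[, "total_cost"] -
                x$outcomes$no_screen[, "total_cost"],
              two_step = x$outcomes$two_step[, "total_cost"] -
                x$outcomes$no_screen[, "total_cost"])
  graphics::plot(range(dq), range(dc), type = "n",
                 xlab = "Incremental QALYs (vs no screening)",
                 ylab = "Incremental cost (2023 CAD, vs no screening)", ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::points(dq[, 1L], dc[, 1L], pch = 1, col = "#1b6ca8")
  graphics::points(dq[, 2L], dc[, 2L], pch = 2, col = "#c0392b")
  graphics::legend("topleft", legend = STRATEGY_LABELS[2:3], pch = 1:2,
                   col = c("#1b6ca8", "#c0392b"), bty = "n")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value \eqn{\lambda}, the probability (over PSA
#' draws) that each strategy has the strictly greatest net monetary benefit
#' \eqn{\lambda \cdot QALYs - cost}; exact ties within a draw split the
#' draw's mass equally among the tied strategies, so the probabilities sum to
#' 1 at every \eqn{\lambda}.
#'
#' @param psa a \code{twin_psa} object with at least one draw.
#' @param wtp numeric vector of willingness-to-pay values (2023 CAD per
#'   QALY).
#' @return a data.frame of class \code{twin_ceac} with columns \code{wtp},
#'   \code{strategy}, \code{probability}.
#' @export
ceac <- function(psa, wtp = seq(0, 200000, by = 5000)) {
  stopifnot(inherits(psa, "twin_psa"), length(wtp) >= 1L)
  qal <- vapply(STRATEGIES, function(s) psa$outcomes[[s]][, "total_qalys"],
                numeric(psa$n))
  cost <- vapply(STRATEGIES, function(s) psa$outcomes[[s]][, "total_cost"],
                 numeric(psa$n))
  if (psa$n == 1L) { qal <- matrix(qal, 1L); cost <- matrix(cost, 1L) }
  out <- lapply(wtp, function(lambda) {
    nmb <- lambda * qal - cost
    best <- apply(nmb, 1L, max)
    tol <- 1e-9 * pmax(1, abs(best))
    isbest <- nmb >= best - tol
    share <- isbest / rowSums(isbest)
    data.frame(wtp = lambda, strategy = STRATEGIES,
               probability = colMeans(share), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("twin_ceac", "data.frame"))
}

#' @export
plot.twin_ceac <- function(x, ...) {
  cols <- c(no_screen = "grey40", one_step = "#1b6ca8", two_step = "#c0392b")
  graphics::plot(range(x$wtp), c(0, 1), type = "n",
                 xlab = "Willingness to pay (2023 CAD per QALY)",
                 ylab = "Probability cost-effective", ...)
  for (s in STRATEGIES) {
    d <- x[x$strategy == s, ]
    graphics::lines(d$wtp, d$probability, col = cols[[s]], lwd = 2)
  }
  graphics::legend("right", legend = STRATEGY_LABELS, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
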