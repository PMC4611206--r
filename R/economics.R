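#' Per-cycle discount factor
#'
#' Annual rate applied in monthly cycles: `(1 + rate)^(-cycle/12)`.
#'
#' @param cycle Cycle index (vectorised).
#' @param annual_rate Annual discount rate (>= 0), e.g. 0.035.
#' @export
discount_factor <- function(cycle, annual_rate) {
  stopifnot(annual_rate >= 0)
  (1 + annual_rate)^(-cycle / 12)
}

#' Discounted costs, QALYs and life-years for one cohort trace
#'
#' State costs accrue on start-of-cycle occupancy and are discounted at the
#' cycle's factor. One-off components for the cryotherapy arm: the procedure
#' cost at cycle 0, the expected adverse-event cost spread uniformly over
#' the adverse-event window (or all at cycle 0 via the parameter-set flag),
#' and the fistula disutility applied to the expected fistula fraction over
#' the same window. The first-line-ADT first-cycle premium (bicalutamide
#' lead-in) is charged on the flow entering the BDFS-with-ADT state.
#' QALYs are occupancy times utility divided by 12, discounted; life-years
#' are undiscounted alive occupancy divided by 12. With the half-cycle
#' correction flag, state occupancy is averaged between cycle start and end.
#'
#' @param trace A [run_cohort()] result.
#' @param sched A [state_cost_schedule()].
#' @param utils_ Per-state utilities ([state_utilities()]).
#' @param draw The [draw_parameters()] result that produced `sched`
#'   (source of the discount rate, adverse-event window and flags).
#' @param applies_sc_costs,applies_ae Charge the procedure / adverse-event
#'   one-offs (defaults follow the strategy that produced the trace).
#' @return Object of class `outcome_summary` with elements `strategy`,
#'   `cost`, `qaly`, `ly`, and `cum_cost` (cumulative discounted mean cost
#'   per patient at the end of each cycle).
#' @export
accumulate <- function(trace, sched, utils_, draw,
                       applies_sc_costs = NULL, applies_ae = NULL) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(sched, "state_cost_schedule"))
  horizon <- nrow(trace$occupancy) - 1
  rate <- draw$scalars$discount_rate_annual
  cycles <- 0:(horizon - 1)
  v <- discount_factor(cycles, rate)
  occ <- trace$occupancy[seq_len(horizon), , drop = FALSE]
  if (isTRUE(draw$flags$half_cycle_correction)) {
    occ <- (occ + trace$occupancy[seq_len(horizon) + 1, , drop = FALSE]) / 2
  }
  is_sc <- if (is.null(applies_sc_costs)) identical(trace$strategy, "SC")
           else applies_sc_costs
  has_ae <- if (is.null(applies_ae)) is_sc else applies_ae

  state_costs <- c(pre_adt = sched$preadt_per_cycle,
                   bdfs_adt = sched$adt_per_cycle,
                   progression = sched$progression_per_cycle,
                   death = 0)
  cost_t <- drop(occ %*% state_costs)

  premium <- sched$adt_first_cycle - sched$adt_per_cycle
  if (!is.null(trace$adt_entries)) {
    cost_t <- cost_t + premium * trace$adt_entries[seq_len(horizon)]
  }
  if (is_sc) cost_t[1] <- cost_t[1] + sched$one_off_sc
  w <- draw$scalars$ae_window_cycles
  if (has_ae) {
    if (isTRUE(draw$flags$ae_costs_at_cycle0)) {
      cost_t[1] <- cost_t[1] + sched$one_off_ae_expected
    } else {
      idx <- seq_len(min(w, horizon))
      cost_t[idx] <- cost_t[idx] + sched$one_off_ae_expected / w
    }
  }
  disc_cost_t <- cost_t * v

  qaly_t <- drop(occ %*% utils_) / 12
  if (has_ae) {
    idx <- seq_len(min(w, horizon))
    dec <- draw$values[["p_fistula"]] * draw$values[["du_fistula"]] / 12
    qaly_t[idx] <- qaly_t[idx] - dec
  }
  disc_qaly_t <- qaly_t * v

  ly <- sum(occ[, c("pre_adt", "bdfs_adt", "progression")]) / 12

  structure(list(strategy = trace$strategy,
                 cost = sum(disc_cost_t),
                 qaly = sum(disc_qaly_t),
                 ly = ly,
                 cum_cost = cumsum(disc_cost_t)),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("<outcome_summary %s: cost %.0f GBP, QALY %.3f, LY %.3f>\n",
              x$strategy, x$cost, x$qaly, x$ly))
  invisible(x)
}

#' Incremental cost-effectiveness of one strategy against a comparator
#'
#' Differences are intervention minus comparator. The intervention is
#' `dominant` when it is cheaper and more effective, `dominated` when
#' costlier and less effective; otherwise the ICER is the cost difference
#' per QALY gained. A zero QALY difference with a non-zero cost difference
#' leaves the ICER undefined.
#'
#' @param intervention,comparator [accumulate()] results on the same
#'   discount basis.
#' @return Object of class `incremental_result` with `delta_cost`,
#'   `delta_qaly`, `classification` and `icer` (NA unless defined).
#' @export
incremental_analysis <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "outcome_summary"),
            inherits(comparator, "outcome_summary"))
  dc <- intervention$cost - comparator$cost
  dq <- intervention$qaly - comparator$qaly
  icer <- NA_real_
  classification <- if (dc < 0 && dq > 0) {
    "dominant"
  } else if (dc > 0 && dq < 0) {
    "dominated"
  } else if (dq == 0) {
    if (dc == 0) "equivalent" else "undefined"
  } else {
    icer <- dc / dq
    "icer"
  }
  structure(list(intervention = intervention$strategy,
                 comparator = comparator$strategy,
                 delta_cost = dc, delta_qaly = dq,
                 classification = classification, icer = icer),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  lab <- switch(x$classification,
                dominant = paste(x$intervention, "dominates"),
                dominated = paste(x$intervention, "dominated"),
                icer = sprintf("ICER %.0f GBP/QALY", x$icer),
                x$classification)
  cat(sprintf("<%s vs %s: dCost %.0f, dQALY %.3f, %s>\n",
              x$intervention, x$comparator, x$delta_cost, x$delta_qaly, lab))
  invisible(x)
}

#' Cost-neutral time point
#'
#' The first time at which the cumulative discounted mean-cost-per-patient
#' curves of two strategies cross, linearly interpolated within the cycle
#' and returned in years; `NA` if they never cross within the horizon, `0`
#' if the curves start equal.
#'
#' @param a,b [accumulate()] results with trajectories of equal length.
#' @export
cost_neutral_time <- function(a, b) {
  stopifnot(inherits(a, "outcome_summary"), inherits(b, "outcome_summary"),
            length(a$cum_cost) == length(b$cum_cost))
  d <- a$cum_cost - b$cum_cost
  if (d[1] == 0) return(0)
  s0 <- sign(d[1])
  cross <- which(sign(d) != s0)[1]
  if (is.na(cross)) return(NA_real_)
  # d changes sign between cycle ends (cross-1) and cross
  d0 <- d[cross - 1]; d1 <- d[cross]
  frac <- if (d1 == d0) 0 else d0 / (d0 - d1)
  ((cross - 1) + frac) / 12
}
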