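#' Treatment strategy definitions
#'
#' Three strategy arms share one four-state structure
#' (pre-ADT, BDFS with ADT, Progression, Death; forward transitions only):
#' \describe{
#'   \item{SC}{salvage cryotherapy: the whole cohort starts pre-ADT
#'     (disease-free after ablation); exit to first-line ADT follows the
#'     spline recurrence model; progression from ADT carries the
#'     post-cryotherapy relative risk; procedure and adverse-event costs
#'     apply.}
#'   \item{ADT_IMMEDIATE}{everyone starts on first-line ADT.}
#'   \item{ADT_20DEF}{a fraction (default 20%) defers ADT ("do nothing"
#'     pre-ADT state, constant monthly uptake), the rest start on ADT.}
#' }
#'
#' @param exit_model Recurrence model for the pre-ADT state of the SC arm:
#'   `"spline"` (use the draw's realised spline) or any object accepted by
#'   [monthly_transition_prob()] (e.g. a [weibull_model()] for scenario 3).
#' @param deferred_fraction Fraction deferring ADT in the mixed strategy.
#' @return Object of class `strategy_definition`.
#' @export
sc_strategy <- function(exit_model = "spline") {
  new_strategy("SC", init = c(1, 0, 0, 0), exit = exit_model,
               use_rr = TRUE, applies_sc_costs = TRUE, applies_ae = TRUE)
}

#' @rdname sc_strategy
#' @export
adt_immediate_strategy <- function() {
  new_strategy("ADT_IMMEDIATE", init = c(0, 1, 0, 0), exit = "constant",
               use_rr = FALSE, applies_sc_costs = FALSE, applies_ae = FALSE)
}

#' @rdname sc_strategy
#' @export
adt_deferred_strategy <- function(deferred_fraction = NULL) {
  new_strategy("ADT_20DEF", init = NULL, exit = "constant",
               use_rr = FALSE, applies_sc_costs = FALSE, applies_ae = FALSE,
               deferred_fraction = deferred_fraction)
}

new_strategy <- function(id, init, exit, use_rr, applies_sc_costs, applies_ae,
                         deferred_fraction = NULL) {
  structure(list(id = id, init = init, exit = exit, use_rr = use_rr,
                 applies_sc_costs = applies_sc_costs, applies_ae = applies_ae,
                 deferred_fraction = deferred_fraction),
            class = "strategy_definition")
}

#' Default comparator set: SC, ADT 20% deferred, ADT immediate
#' @export
default_strategies <- function() {
  list(sc_strategy(), adt_deferred_strategy(), adt_immediate_strategy())
}

.states <- c("pre_adt", "bdfs_adt", "progression", "death")

strategy_init <- function(s, draw) {
  if (!is.null(s$init)) return(s$init)
  f <- if (!is.null(s$deferred_fraction)) s$deferred_fraction
       else draw$scalars$deferred_fraction
  c(f, 1 - f, 0, 0)
}

# Per-cycle clinical/mortality probabilities for a strategy arm.
cycle_probs <- function(s, draw, mort, horizon) {
  cycles <- 0:(horizon - 1)
  age <- draw$scalars$start_age + cycles / 12
  q_bg <- monthly_death_prob(mort$life_table, age)
  q_pc <- monthly_pc_excess_hazard(mort$pc_table, age)
  q_prog_death <- combine_monthly_probs(q_bg, q_pc)
  p_exit <- if (identical(s$exit, "spline")) {
    monthly_transition_prob(draw$spline, cycles)
  } else if (identical(s$exit, "constant")) {
    rep(draw$values[["p_deferred_to_adt"]], horizon)
  } else {
    monthly_transition_prob(s$exit, cycles)
  }
  rr <- if (s$use_rr) draw$values[["rr_progression_post_sc"]] else 1
  p_prog <- 1 - (1 - draw$values[["p_adt_to_progression"]])^rr
  list(q_bg = q_bg, q_prog_death = q_prog_death, p_exit = p_exit,
       p_prog = p_prog, age = c(age, draw$scalars$start_age + horizon / 12))
}

#' Single-cycle transition matrix
#'
#' Row-stochastic 4x4 matrix over (pre-ADT, BDFS-ADT, Progression, Death)
#' for one cycle of one arm. Competing within-cycle events are resolved by
#' applying death first and the clinical transition among survivors.
#' Prostate-cancer mortality adds to background mortality in the
#' Progression state only.
#'
#' @param s A strategy (see [sc_strategy()]).
#' @param draw A [draw_parameters()] result.
#' @param cycle Cycle index (>= 0).
#' @param mort A [mortality_inputs()] bundle.
#' @return 4x4 matrix with dimnames over the states.
#' @export
transition_matrix <- function(s, draw, cycle, mort) {
  stopifnot(length(cycle) == 1L, cycle >= 0,
            cycle < draw$scalars$horizon_cycles)
  cp <- cycle_probs(s, draw, mort, cycle + 1)
  i <- cycle + 1
  q <- cp$q_bg[i]; qp <- cp$q_prog_death[i]
  pe <- cp$p_exit[i]; pp <- cp$p_prog
  m <- rbind(
    pre_adt = c((1 - q) * (1 - pe), (1 - q) * pe, 0, q),
    bdfs_adt = c(0, (1 - q) * (1 - pp), (1 - q) * pp, q),
    progression = c(0, 0, 1 - qp, qp),
    death = c(0, 0, 0, 1))
  colnames(m) <- .states
  if (any(abs(rowSums(m) - 1) > 1e-12)) {
    stop("internal error: transition matrix rows do not sum to 1",
         call. = FALSE)
  }
  m
}

#' Propagate the cohort through the Markov model
#'
#' Row 0 of the trace is the initial occupancy; row `t + 1` is row `t`
#' multiplied by the cycle-`t` transition matrix. Age advances by 1/12 year
#' per cycle. The trace also records the flow of patients newly entering
#' the BDFS-with-ADT state each cycle (used for the first-cycle ADT cost
#' premium).
#'
#' @inheritParams transition_matrix
#' @param horizon Number of monthly cycles (default from the draw).
#' @return Object of class `cohort_trace`: list with `occupancy`
#'   ((horizon+1) x 4 matrix of proportions), `age`, `adt_entries`,
#'   `strategy`.
#' @export
run_cohort <- function(s, draw, mort, horizon = NULL) {
  stopifnot(inherits(s, "strategy_definition"), inherits(draw, "parameter_draw"))
  if (is.null(horizon)) horizon <- draw$scalars$horizon_cycles
  cp <- cycle_probs(s, draw, mort, horizon)
  occ <- matrix(0, nrow = horizon + 1, ncol = 4,
                dimnames = list(NULL, .states))
  occ[1, ] <- strategy_init(s, draw)
  entries <- numeric(horizon + 1)
  entries[1] <- occ[1, "bdfs_adt"]
  pre <- occ[1, 1]; bdfs <- occ[1, 2]; prog <- occ[1, 3]; dead <- occ[1, 4]
  pp <- cp$p_prog
  for (t in seq_len(horizon)) {
    q <- cp$q_bg[t]; qp <- cp$q_prog_death[t]; pe <- cp$p_exit[t]
    inflow_bdfs <- pre * (1 - q) * pe
    new_dead <- dead + pre * q + bdfs * q + prog * qp
    new_prog <- prog * (1 - qp) + bdfs * (1 - q) * pp
    new_bdfs <- bdfs * (1 - q) * (1 - pp) + inflow_bdfs
    new_pre <- pre * (1 - q) * (1 - pe)
    pre <- new_pre; bdfs <- new_bdfs; prog <- new_prog; dead <- new_dead
    occ[t + 1, ] <- c(pre, bdfs, prog, dead)
    entries[t + 1] <- inflow_bdfs
  }
  structure(list(occupancy = occ, age = cp$age, adt_entries = entries,
                 strategy = s$id),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  h <- nrow(x$occupancy) - 1
  cat(sprintf("<cohort_trace %s: %d cycles, final death %.4f>\n",
              x$strategy, h, x$occupancy[h + 1, "death"]))
  invisible(x)
}

#' Export a cohort trace to CSV
#'
#' Columns: `cycle,age,pre_adt,bdfs_adt,progression,death`.
#' @param trace A [run_cohort()] result.
#' @param path CSV path.
#' @export
write_cohort_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  df <- data.frame(cycle = seq_len(nrow(trace$occupancy)) - 1,
                   age = trace$age, trace$occupancy, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n` individuals through the identical transition rules and
#' returns the occupancy estimate in the same `cohort_trace` form. Used to
#' validate [run_cohort()]: the cohort trace is the exact expectation of
#' this stochastic process, so occupancy estimates converge at binomial
#' Monte-Carlo rate.
#'
#' @inheritParams run_cohort
#' @param n Number of simulated individuals.
#' @param seed Integer seed.
#' @export
microsim_oracle <- function(s, draw, mort, n, seed, horizon = NULL) {
  stopifnot(n >= 1)
  if (is.null(horizon)) horizon <- draw$scalars$horizon_cycles
  cp <- cycle_probs(s, draw, mort, horizon)
  init <- strategy_init(s, draw)
  set.seed(as.integer(seed))
  state <- sample.int(4, n, replace = TRUE, prob = init)
  occ <- matrix(0, nrow = horizon + 1, ncol = 4,
                dimnames = list(NULL, .states))
  occ[1, ] <- tabulate(state, 4) / n
  pp <- cp$p_prog
  for (t in seq_len(horizon)) {
    alive <- which(state != 4L)
    if (length(alive)) {
      st <- state[alive]
      u_death <- stats::runif(length(alive))
      q <- ifelse(st == 3L, cp$q_prog_death[t], cp$q_bg[t])
      dies <- u_death < q
      state[alive[dies]] <- 4L
      surv <- alive[!dies]
      if (length(surv)) {
        st <- state[surv]
        u_move <- stats::runif(length(surv))
        p_move <- ifelse(st == 1L, cp$p_exit[t], ifelse(st == 2L, pp, 0))
        moves <- u_move < p_move
        state[surv[moves]] <- state[surv[moves]] + 1L
      }
    }
    occ[t + 1, ] <- tabulate(state, 4) / n
  }
  structure(list(occupancy = occ, age = cp$age,
                 adt_entries = NULL, strategy = s$id),
            class = "cohort_trace")
}
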