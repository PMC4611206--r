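#' Deterministic (point-estimate) model run
#'
#' Runs every strategy at the parameter point estimates and compares the
#' first-listed strategy against each comparator.
#'
#' @param ps A [build_parameter_set()] result.
#' @param strategies List of strategies; the first is the intervention.
#' @param mort A [mortality_inputs()] bundle.
#' @param draw Optional pre-made [draw_parameters()] result (e.g. one PSA
#'   draw); defaults to the point estimates.
#' @return List with `outcomes` (named list of [accumulate()] summaries),
#'   `incremental` (intervention vs each comparator, named by comparator)
#'   and `cost_neutral_years` (first comparator).
#' @examples
#' \donttest{
#' res <- run_base_case(default_parameter_set())
#' res$incremental$ADT_20DEF
#' }
#' @export
run_base_case <- function(ps, strategies = default_strategies(),
                          mort = default_mortality(), draw = NULL) {
  if (is.null(draw)) draw <- draw_parameters(ps, point_estimate = TRUE)
  sched <- state_cost_schedule(draw)
  utils_ <- state_utilities(draw)
  outcomes <- lapply(strategies, function(s) {
    accumulate(run_cohort(s, draw, mort), sched, utils_, draw,
               applies_sc_costs = s$applies_sc_costs,
               applies_ae = s$applies_ae)
  })
  names(outcomes) <- vapply(strategies, `[[`, character(1), "id")
  comparators <- names(outcomes)[-1]
  incremental <- lapply(comparators, function(id) {
    incremental_analysis(outcomes[[1]], outcomes[[id]])
  })
  names(incremental) <- comparators
  cn <- if (length(comparators)) {
    cost_neutral_time(outcomes[[1]], outcomes[[comparators[1]]])
  } else {
    NA_real_
  }
  list(outcomes = outcomes, incremental = incremental,
       cost_neutral_years = cn)
}

#' Results table in the reporting layout
#'
#' One row per strategy: mean cost, life-years, QALYs, incremental cost and
#' QALYs against the intervention, classification/ICER and cost-neutral
#' time.
#'
#' @param res A [run_base_case()] result.
#' @export
results_table <- function(res) {
  ids <- names(res$outcomes)
  rows <- lapply(ids, function(id) {
    o <- res$outcomes[[id]]
    inc <- res$incremental[[id]]
    data.frame(strategy = id, cost = o$cost, ly = o$ly, qaly = o$qaly,
               inc_cost = if (is.null(inc)) NA_real_ else -inc$delta_cost,
               inc_qaly = if (is.null(inc)) NA_real_ else -inc$delta_qaly,
               icer_or_dominance = if (is.null(inc)) NA_character_
               else if (inc$classification == "icer")
                 sprintf("%.0f", inc$icer)
               else inc$classification,
               cost_neutral_years = if (is.null(inc)) NA_real_
               else cost_neutral_time(res$outcomes[[ids[1]]], o))
  })
  do.call(rbind, rows)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run: the full parameter
#' configuration, strategy ids, seed, iteration count and package version.
#'
#' @param path Output path.
#' @param ps Parameter set used.
#' @param strategies Strategies used.
#' @param seed,n_iter PSA settings (NULL for deterministic runs).
#' @param extra Named list of additional fields.
#' @export
write_run_manifest <- function(path, ps, strategies, seed = NULL,
                               n_iter = NULL, extra = list()) {
  manifest <- c(list(
    package = "cryocea",
    version = as.character(utils::packageVersion("cryocea")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed, n_iterations = n_iter,
    strategies = vapply(strategies, `[[`, character(1), "id"),
    scalars = ps$scalars,
    flags = ps$flags,
    spline_knots_log_months = ps$spline_knots,
    unit_costs = as.list(ps$unit_costs),
    parameters = lapply(ps$dists, function(d) {
      list(family = d$family, mean = d$mean, se = d$se)
    })), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Export CEAC / CE-plane data
#'
#' `write_ceac()` writes `wtp,strategy,probability`; `write_ce_plane()`
#' writes `iteration,delta_cost,delta_qaly`.
#'
#' @param x A [ceac()] or [ce_plane()] result.
#' @param path CSV path.
#' @export
write_ceac <- function(x, path) {
  stopifnot(inherits(x, "ceac_curve"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ceac
#' @export
write_ce_plane <- function(x, path) {
  utils::write.csv(x[c("iteration", "delta_cost", "delta_qaly")], path,
                   row.names = FALSE)
  invisible(path)
}
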