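#' Model parameter set
#'
#' Houses every model input with its uncertainty distribution: monthly
#' transition probabilities, the spline coefficients for post-cryotherapy
#' recurrence, adverse-event probabilities and costs, cryotherapy resource
#' use with fixed unit costs, first- and second-line ADT cost components,
#' and health-state utilities. Built from a JSON or YAML configuration file
#' by [build_parameter_set()]; the packaged base case lives at
#' `system.file("extdata", "base_case.json", package = "cryocea")`.
#'
#' @name parameter_set
NULL

# Parameters drawn from uncertainty distributions, with family constraints.
# (name, family) pairs; mean/se come from the config.
.dist_params <- c(
  p_metastatic_in_progression = "beta",
  p_deferred_to_adt = "beta",
  p_adt_to_progression = "beta",
  rr_progression_post_sc = "lognormal",
  spline_gamma0 = "normal",
  spline_gamma1 = "normal",
  spline_gamma2 = "normal",
  p_fistula = "beta", p_incontinence = "beta", p_retention = "beta",
  p_luts = "beta", p_perineal_pain = "beta", p_haematuria = "beta",
  p_stricture = "beta", p_hot_flush = "beta",
  cost_fistula = "gamma", cost_incontinence = "gamma",
  cost_retention = "gamma", cost_haematuria = "gamma",
  cost_stricture = "gamma",
  cost_luts = "fixed", cost_perineal_pain = "fixed",
  cost_hot_flush_per_cycle = "fixed",
  surgeon_hours = "gamma", theatre_hours = "gamma",
  overnight_stays = "gamma", catheter_hours = "gamma",
  delivery_hours = "gamma",
  u_dfs = "beta", u_progression_metastatic = "beta",
  u_progression_nonmetastatic = "beta", du_fistula = "beta")

.scalar_params <- c("start_age", "cohort_size", "horizon_cycles",
                    "cycle_length_months", "discount_rate_annual",
                    "deferred_fraction", "ae_window_cycles")

.unit_cost_params <- c("ultrasound", "theatre_per_hour", "consultant_per_hour",
                       "additional_theatre", "needle_kit", "overnight_stay",
                       "nurse_per_hour", "sc_medication", "goserelin",
                       "bicalutamide", "abiraterone_per_cycle", "leuprorelin",
                       "flutamide")

# Seven acute cryotherapy adverse events (hot flushes are an ADT side effect
# handled inside the ADT cycle cost).
.acute_ae <- c("fistula", "incontinence", "retention", "luts",
               "perineal_pain", "haematuria", "stricture")

#' Build a validated parameter set from a configuration file
#'
#' Reads JSON (`.json`) or YAML (`.yml`/`.yaml`), checks every required key
#' and every range constraint, and reports all violations together.
#'
#' @param config Path to a JSON/YAML file, or an already-parsed nested list
#'   with the same structure.
#' @return An object of class `parameter_set`.
#' @examples
#' ps <- default_parameter_set()
#' ps$dists$p_adt_to_progression
#' @export
build_parameter_set <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("parameter config not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  scalars <- config$model
  for (k in .scalar_params) {
    v <- scalars[[k]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      note("model.", k, ": missing or not a finite number")
    }
  }
  if (is.numeric(scalars$discount_rate_annual) &&
      isTRUE(scalars$discount_rate_annual < 0)) {
    note("model.discount_rate_annual: must be >= 0")
  }
  if (is.numeric(scalars$deferred_fraction) &&
      (isTRUE(scalars$deferred_fraction < 0) ||
       isTRUE(scalars$deferred_fraction > 1))) {
    note("model.deferred_fraction: must lie in [0,1]")
  }

  dists <- list()
  for (k in names(.dist_params)) {
    raw <- config$parameters[[k]]
    if (is.null(raw)) {
      note("parameters.", k, ": missing")
      next
    }
    fam <- if (is.null(raw$family)) .dist_params[[k]] else raw$family
    if (!identical(fam, .dist_params[[k]])) {
      note("parameters.", k, ": family must be '", .dist_params[[k]],
           "', got '", fam, "'")
      next
    }
    if (is.null(raw$mean) || !is.numeric(raw$mean)) {
      note("parameters.", k, ": mean missing or non-numeric")
      next
    }
    se <- if (is.null(raw$se)) 0 else raw$se
    d <- tryCatch(dist_spec(fam, raw$mean, se, name = k),
                  error = function(e) conditionMessage(e))
    if (is.character(d)) note(d) else dists[[k]] <- d
  }

  unit_costs <- numeric(0)
  for (k in .unit_cost_params) {
    v <- config$unit_costs[[k]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      note("unit_costs.", k, ": missing or not a finite number")
    } else if (v < 0) {
      note("unit_costs.", k, ": must be >= 0, got ", v)
    } else {
      unit_costs[[k]] <- v
    }
  }

  knots <- config$spline_knots_log_months
  if (is.null(knots) || length(knots) != 3L || !is.numeric(knots)) {
    note("spline_knots_log_months: need three numeric log-month knots")
  } else if (any(diff(knots) <= 0)) {
    note("spline_knots_log_months: knots must be strictly increasing")
  }

  flags <- list(
    metastatic_cost_same_as_nonmetastatic =
      isTRUE(config$flags$metastatic_cost_same_as_nonmetastatic),
    subtract_pc_from_background =
      isTRUE(config$flags$subtract_pc_from_background),
    half_cycle_correction = isTRUE(config$flags$half_cycle_correction),
    ae_costs_at_cycle0 = isTRUE(config$flags$ae_costs_at_cycle0))

  if (length(problems)) {
    stop("invalid parameter configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  ps <- structure(list(scalars = scalars[.scalar_params], dists = dists,
                       unit_costs = unit_costs, spline_knots = as.numeric(knots),
                       flags = flags),
                  class = "parameter_set")
  validate_parameter_set(ps)
}

validate_parameter_set <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  problems <- character(0)
  s <- ps$scalars
  if (s$start_age < 18 || s$start_age > 100) {
    problems <- c(problems, "model.start_age: implausible (expect 18-100)")
  }
  if (s$horizon_cycles < 1 || s$horizon_cycles != round(s$horizon_cycles)) {
    problems <- c(problems, "model.horizon_cycles: must be a positive integer")
  }
  for (k in names(ps$dists)) {
    d <- ps$dists[[k]]
    if (d$family == "beta" && (d$mean <= 0 || d$mean >= 1)) {
      problems <- c(problems, paste0("parameters.", k,
                                     ": probability/utility out of (0,1)"))
    }
    if (startsWith(k, "cost_") && d$mean < 0) {
      problems <- c(problems, paste0("parameters.", k, ": cost must be >= 0"))
    }
  }
  if (length(problems)) {
    stop("invalid parameter set:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  start age %g y, horizon %g monthly cycles, discount %.1f%%/y\n",
              x$scalars$start_age, x$scalars$horizon_cycles,
              100 * x$scalars$discount_rate_annual))
  cat(sprintf("  %d distributional parameters, %d fixed unit costs\n",
              length(x$dists), length(x$unit_costs)))
  invisible(x)
}

#' Packaged base-case parameter set
#'
#' @return A `parameter_set` built from the packaged base-case configuration.
#' @export
default_parameter_set <- function() {
  build_parameter_set(system.file("extdata", "base_case.json",
                                  package = "cryocea", mustWork = TRUE))
}

# -- drawing -----------------------------------------------------------------

# Deterministic per-parameter sub-stream seed: a small string hash folded
# with the base seed, kept below 2^31. Adding or reordering parameters does
# not perturb the draws of the others.
substream_seed <- function(seed, name) {
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 1977326743
  as.integer((seed + h) %% .Machine$integer.max)
}

#' Draw one realisation of every parameter
#'
#' Each distributional parameter is drawn from its family on an independent
#' sub-stream derived from `seed` and the parameter name, so draws are
#' reproducible per seed and insensitive to the presence of other
#' parameters. With `point_estimate = TRUE` (or when all SEs are zero) the
#' draw equals the point estimates.
#'
#' @param ps A [build_parameter_set()] result.
#' @param seed Integer seed (required unless `point_estimate = TRUE`).
#' @param point_estimate If `TRUE`, return means instead of random draws.
#' @return An object of class `parameter_draw`: list with numeric vector
#'   `values`, a realised [spline_model()], scalars, unit costs and flags.
#' @export
draw_parameters <- function(ps, seed = NULL, point_estimate = FALSE) {
  stopifnot(inherits(ps, "parameter_set"))
  if (point_estimate) {
    values <- vapply(ps$dists, function(d) d$mean, numeric(1))
  } else {
    if (is.null(seed)) stop("draw_parameters: seed required", call. = FALSE)
    values <- vapply(names(ps$dists), function(k) {
      d <- ps$dists[[k]]
      if (d$family == "fixed" || d$se == 0) return(d$mean)
      old <- get0(".Random.seed", envir = globalenv())
      set.seed(substream_seed(seed, k))
      out <- draw_dist(d, 1L)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      out
    }, numeric(1))
  }
  # clamp realised probabilities/utilities and costs (beta/gamma draws are
  # inside their supports already; this guards configured point estimates
  # and any future family changes)
  probs <- grepl("^(p_|u_|du_)", names(values))
  values[probs] <- pmin(pmax(values[probs], 0), 1)
  costs <- grepl("^cost_", names(values))
  values[costs] <- pmax(values[costs], 0)

  structure(list(
    values = values,
    spline = spline_model(values[["spline_gamma0"]], values[["spline_gamma1"]],
                          values[["spline_gamma2"]], knots = ps$spline_knots),
    scalars = ps$scalars, unit_costs = ps$unit_costs, flags = ps$flags,
    seed = seed),
    class = "parameter_draw")
}

#' @export
print.parameter_draw <- function(x, ...) {
  cat("<parameter_draw>", if (!is.null(x$seed)) paste0(" seed ", x$seed), "\n")
  print(utils::head(round(x$values, 5), 8))
  invisible(x)
}

# -- cost roll-ups -----------------------------------------------------------

#' Expected per-cycle cost of second-line therapy in the Progression state
#'
#' Mixture of the metastatic regimen (abiraterone) and the non-metastatic
#' regimen (leuprorelin-based) weighted by the proportion of progression
#' patients with confirmed metastases.
#'
#' @param p_met Proportion with confirmed metastases, in `[0, 1]`.
#' @param cost_met Monthly cost of the metastatic regimen (GBP).
#' @param cost_nonmet Monthly cost of the non-metastatic regimen (GBP).
#' @return Expected cost per patient-cycle (GBP).
#' @examples
#' progression_cycle_cost(0.4, 2930, 95.44)  # 1229.27
#' @export
progression_cycle_cost <- function(p_met, cost_met, cost_nonmet) {
  stopifnot(p_met >= 0, p_met <= 1)
  p_met * cost_met + (1 - p_met) * cost_nonmet
}

#' Mean utility of the Progression state
#'
#' Metastatic/non-metastatic mixture of health-state utilities.
#'
#' @param p_met Proportion with confirmed metastases.
#' @param u_met,u_nonmet Utilities of metastatic and non-metastatic
#'   progression, in `[0, 1]`.
#' @export
progression_utility <- function(p_met, u_met, u_nonmet) {
  stopifnot(p_met >= 0, p_met <= 1, u_met >= 0, u_met <= 1,
            u_nonmet >= 0, u_nonmet <= 1)
  p_met * u_met + (1 - p_met) * u_nonmet
}

#' Per-state, per-cycle cost schedule consumed by the engine
#'
#' Rolls the unit costs and realised resource-use quantities up into the
#' schedule of state/event costs:
#' \describe{
#'   \item{one_off_sc}{cryotherapy procedure (ultrasound, surgeon and theatre
#'     time, consumables, overnight stays, catheter) plus peri-operative
#'     medication; charged once at cycle 0 of the cryotherapy arm.}
#'   \item{one_off_ae_expected}{probability-weighted cost of the seven acute
#'     adverse events, charged over the adverse-event window.}
#'   \item{adt_first_cycle / adt_per_cycle}{first-line ADT with and without
#'     the bicalutamide lead-in; the per-cycle figure includes the expected
#'     hot-flush treatment cost and nurse delivery.}
#'   \item{progression_per_cycle}{expected second-line cost
#'     ([progression_cycle_cost()]).}
#'   \item{preadt_per_cycle}{0 — watchful waiting.}
#' }
#'
#' @param draw A [draw_parameters()] result.
#' @return Object of class `state_cost_schedule` (a named list of costs).
#' @examples
#' sched <- state_cost_schedule(draw_parameters(default_parameter_set(),
#'                                              point_estimate = TRUE))
#' round(sched$one_off_sc, 2)
#' @export
state_cost_schedule <- function(draw) {
  stopifnot(inherits(draw, "parameter_draw"))
  v <- draw$values
  u <- draw$unit_costs

  sc_surgery <- u[["ultrasound"]] +
    u[["consultant_per_hour"]] * v[["surgeon_hours"]] +
    u[["theatre_per_hour"]] * v[["theatre_hours"]] +
    u[["additional_theatre"]] + u[["needle_kit"]] +
    u[["overnight_stay"]] * v[["overnight_stays"]] +
    u[["nurse_per_hour"]] * v[["catheter_hours"]]
  one_off_sc <- sc_surgery + u[["sc_medication"]]

  ae_p <- v[paste0("p_", .acute_ae)]
  ae_c <- v[paste0("cost_", .acute_ae)]
  one_off_ae_expected <- sum(ae_p * ae_c)

  delivery <- u[["nurse_per_hour"]] * v[["delivery_hours"]]
  adt_per_cycle <- u[["goserelin"]] +
    v[["p_hot_flush"]] * v[["cost_hot_flush_per_cycle"]] + delivery
  adt_first_cycle <- adt_per_cycle + u[["bicalutamide"]]

  secondline_nonmet <- u[["leuprorelin"]] +
    v[["p_hot_flush"]] * u[["flutamide"]] + delivery
  secondline_met <- if (draw$flags$metastatic_cost_same_as_nonmetastatic) {
    secondline_nonmet
  } else {
    u[["abiraterone_per_cycle"]]
  }

  structure(list(
    one_off_sc = unname(one_off_sc),
    one_off_ae_expected = unname(one_off_ae_expected),
    adt_first_cycle = unname(adt_first_cycle),
    adt_per_cycle = unname(adt_per_cycle),
    secondline_met = unname(secondline_met),
    secondline_nonmet = unname(secondline_nonmet),
    progression_per_cycle = unname(progression_cycle_cost(
      v[["p_metastatic_in_progression"]], secondline_met, secondline_nonmet)),
    preadt_per_cycle = 0),
    class = "state_cost_schedule")
}

#' @export
print.state_cost_schedule <- function(x, ...) {
  cat("<state_cost_schedule> (GBP)\n")
  for (k in names(x)) cat(sprintf("  %-22s %10.2f\n", k, x[[k]]))
  invisible(x)
}

#' Health-state utilities realised from a draw
#'
#' Returns the per-state annual utility weights in state order
#' (pre-ADT, BDFS-ADT, Progression, Death). The pre-ADT and BDFS-with-ADT
#' states share the disease-free-survival utility.
#'
#' @param draw A [draw_parameters()] result.
#' @return Named numeric vector of length 4.
#' @export
state_utilities <- function(draw) {
  v <- draw$values
  c(pre_adt = unname(v[["u_dfs"]]),
    bdfs_adt = unname(v[["u_dfs"]]),
    progression = unname(progression_utility(
      v[["p_metastatic_in_progression"]],
      v[["u_progression_metastatic"]], v[["u_progression_nonmetastatic"]])),
    death = 0)
}
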