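#' Restricted-cubic-spline survival model on the log-cumulative-hazard scale
#'
#' Flexible parametric (Royston–Parmar) proportional-hazards model with one
#' internal knot: `log H(t) = gamma0 + gamma1 * s0(log t) + gamma2 * s1(log t)`
#' where `s0(x) = x` and `s1` is the restricted cubic basis ([rcs_basis()]).
#' This drives the time-dependent transition from the post-cryotherapy
#' disease-free state to first-line ADT.
#'
#' @param gamma0,gamma1,gamma2 Spline coefficients (intercept, coefficient on
#'   `log t`, coefficient on the cubic basis).
#' @param knots Three strictly increasing knots on the log-time scale
#'   (lower boundary, internal, upper boundary), in log-months.
#' @param se Optional named numeric vector of coefficient standard errors
#'   (`gamma0`, `gamma1`, `gamma2`).
#' @param time_unit Time unit of `t`; only `"months"` is used by the engine.
#' @return An object of class `spline_model`.
#' @examples
#' m <- spline_model(-4.58, 1.01, 0.303, knots = log(c(1, 24, 120)))
#' cumulative_hazard(m, 12)
#' @export
spline_model <- function(gamma0, gamma1, gamma2, knots, se = NULL,
                         time_unit = "months") {
  stopifnot(length(knots) == 3L, is.numeric(knots))
  if (any(diff(knots) <= 0)) {
    stop("spline knots must be strictly increasing", call. = FALSE)
  }
  structure(list(gamma = c(gamma0 = unname(gamma0), gamma1 = unname(gamma1),
                           gamma2 = unname(gamma2)),
                 knots = as.numeric(knots), se = se, time_unit = time_unit),
            class = "spline_model")
}

#' @export
print.spline_model <- function(x, ...) {
  cat("Restricted cubic spline on log cumulative hazard (1 internal knot)\n")
  cat(sprintf("  gamma: %.4f  %.4f  %.4f\n",
              x$gamma[1], x$gamma[2], x$gamma[3]))
  cat(sprintf("  knots (log %s): %.4f  %.4f  %.4f\n",
              x$time_unit, x$knots[1], x$knots[2], x$knots[3]))
  if (!is.null(x$se)) {
    cat(sprintf("  se:    %.4f  %.4f  %.4f\n", x$se[1], x$se[2], x$se[3]))
  }
  invisible(x)
}

#' Restricted cubic spline basis with one internal knot
#'
#' `s0 = log_t` and
#' `s1 = (x - k_int)+^3 - lambda * (x - k_lo)+^3 - (1 - lambda) * (x - k_hi)+^3`
#' with `lambda = (k_hi - k_int) / (k_hi - k_lo)`, which makes `s1` linear
#' beyond the boundary knots.
#'
#' @param log_t Numeric vector of log times.
#' @param knots Three increasing knots on the log-time scale.
#' @return Matrix with columns `s0`, `s1`.
#' @export
rcs_basis <- function(log_t, knots) {
  stopifnot(length(knots) == 3L)
  if (any(diff(knots) <= 0)) {
    stop("spline knots must be strictly increasing", call. = FALSE)
  }
  lam <- (knots[3] - knots[2]) / (knots[3] - knots[1])
  pos3 <- function(u) pmax(u, 0)^3
  s1 <- pos3(log_t - knots[2]) - lam * pos3(log_t - knots[1]) -
    (1 - lam) * pos3(log_t - knots[3])
  cbind(s0 = log_t, s1 = s1)
}

#' Cumulative hazard and survival of a spline model
#'
#' `H(t) = exp(gamma0 + gamma1 * s0(log t) + gamma2 * s1(log t))`;
#' `S(t) = exp(-H(t))`. Note `H` as written is not guaranteed monotone for
#' an arbitrary coefficient draw; the cycle engine uses
#' [monthly_transition_prob()], which floors negative increments.
#'
#' @param m A [spline_model()].
#' @param t Positive times (months).
#' @return Numeric vector of cumulative hazards.
#' @export
cumulative_hazard <- function(m, t) {
  stopifnot(inherits(m, "spline_model"))
  if (any(t <= 0)) stop("cumulative_hazard: t must be > 0", call. = FALSE)
  b <- rcs_basis(log(t), m$knots)
  unname(exp(m$gamma[[1]] + m$gamma[[2]] * b[, "s0"] + m$gamma[[3]] * b[, "s1"]))
}

#' @rdname cumulative_hazard
#' @export
spline_survival <- function(m, t) exp(-cumulative_hazard(m, t))

#' Monthly transition probability implied by a spline survival model
#'
#' For cycle `c` (months `c` to `c + 1`), `p = 1 - exp(-dH)` with
#' `dH = max(0, H(c + 1) - H(c))` and `H(0) = 0`. Flooring the increment at
#' zero guarantees a valid probability even when a probabilistic coefficient
#' draw makes the fitted log-cumulative-hazard locally decreasing.
#'
#' @param m A [spline_model()] (or any object with a
#'   `monthly_transition_prob` method, e.g. [weibull_model()]).
#' @param cycle Integer vector of cycle indices (>= 0).
#' @return Vector of probabilities in `[0, 1]`.
#' @export
monthly_transition_prob <- function(m, cycle) {
  UseMethod("monthly_transition_prob")
}

#' @export
monthly_transition_prob.spline_model <- function(m, cycle) {
  stopifnot(all(cycle >= 0))
  h1 <- cumulative_hazard(m, cycle + 1)
  h0 <- ifelse(cycle == 0, 0, cumulative_hazard(m, pmax(cycle, 1e-12)))
  1 - exp(-pmax(h1 - h0, 0))
}

#' @export
monthly_transition_prob.function <- function(m, cycle) {
  p <- vapply(cycle, m, numeric(1))
  stopifnot(all(p >= 0 & p <= 1))
  p
}

#' Weibull recurrence model (alternative to the spline)
#'
#' Cumulative hazard `H(t) = (t / scale)^shape`. Used as the pluggable
#' alternative recurrence model in scenario 3, where published alternative
#' disease-free-survival data replace the base-case spline.
#'
#' @param shape,scale Weibull shape and scale (scale in months).
#' @return Object of class `weibull_model`.
#' @export
weibull_model <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  structure(list(shape = shape, scale = scale), class = "weibull_model")
}

#' @export
monthly_transition_prob.weibull_model <- function(m, cycle) {
  stopifnot(all(cycle >= 0))
  H <- function(t) (t / m$scale)^m$shape
  1 - exp(-pmax(H(cycle + 1) - H(cycle), 0))
}

#' Fit the spline survival model to right-censored Kaplan-Meier style data
#'
#' Maximum-likelihood Royston–Parmar fit (via [flexsurv::flexsurvspline()]
#' with `scale = "hazard"`, one internal knot). Knots default to the extremes
#' of the uncensored log event times (boundaries) and the
#' `internal_knot_quantile` quantile of uncensored log event times, the
#' standard flexible-parametric choice; alternatively pass `knots` to fix
#' all three.
#'
#' @param data Data frame with columns `time_months` (> 0) and `event`
#'   (1 = biochemical recurrence, 0 = censored).
#' @param internal_knot_quantile Quantile of uncensored log event times at
#'   which to place the internal knot (default median).
#' @param knots Optional fixed knots (length 3, log-months); overrides the
#'   data-driven placement.
#' @return A [spline_model()] carrying coefficient standard errors.
#' @export
fit_spline_km <- function(data, internal_knot_quantile = 0.5, knots = NULL) {
  data <- validate_km_data(data)
  n_events <- sum(data$event == 1)
  if (n_events < 10L) {
    stop("fit_spline_km: need at least 10 events, got ", n_events,
         call. = FALSE)
  }
  logt_ev <- log(data$time_months[data$event == 1])
  if (is.null(knots)) {
    bknots <- range(logt_ev)
    kint <- unname(stats::quantile(logt_ev, internal_knot_quantile, type = 7))
    knots <- c(bknots[1], kint, bknots[2])
  }
  stopifnot(length(knots) == 3L)
  fit <- flexsurv::flexsurvspline(
    survival::Surv(time_months, event) ~ 1, data = data,
    knots = knots[2], bknots = knots[c(1, 3)], scale = "hazard")
  co <- stats::coef(fit)
  ses <- sqrt(diag(stats::vcov(fit)))
  spline_model(co[["gamma0"]], co[["gamma1"]], co[["gamma2"]],
               knots = knots,
               se = c(gamma0 = ses[["gamma0"]], gamma1 = ses[["gamma1"]],
                      gamma2 = ses[["gamma2"]]))
}

validate_km_data <- function(data) {
  data <- as.data.frame(data)
  req <- c("time_months", "event")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("KM data must have columns time_months,event; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(data$time_months <= 0)) {
    stop("KM data: times must be positive", call. = FALSE)
  }
  if (!all(data$event %in% c(0, 1))) {
    stop("KM data: event must be 0 or 1", call. = FALSE)
  }
  data
}

#' Read/write Kaplan-Meier disease-free-survival data
#'
#' CSV schema: header `time_months,event`.
#' @param path File path.
#' @param data Data frame with columns `time_months`, `event`.
#' @return `read_km_data()` returns a validated data frame.
#' @export
read_km_data <- function(path) {
  validate_km_data(utils::read.csv(path))
}

#' @rdname read_km_data
#' @export
write_km_data <- function(data, path) {
  utils::write.csv(validate_km_data(data), path, row.names = FALSE)
  invisible(path)
}

#' Serialise a fitted spline model to JSON (and back)
#'
#' @param m A [spline_model()].
#' @param path File path.
#' @export
write_spline_model <- function(m, path) {
  stopifnot(inherits(m, "spline_model"))
  jsonlite::write_json(
    list(gamma = as.list(m$gamma), knots = m$knots,
         se = if (is.null(m$se)) NULL else as.list(m$se),
         time_unit = m$time_unit),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spline_model
#' @export
read_spline_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spline_model(x$gamma$gamma0, x$gamma$gamma1, x$gamma$gamma2,
               knots = x$knots,
               se = if (is.null(x$se)) NULL else unlist(x$se),
               time_unit = x$time_unit)
}
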