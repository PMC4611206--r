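#' Synthetic external inputs
#'
#' The analysis needs three external inputs the package cannot ship from
#' their primary sources: an age-specific male all-cause life table, an
#' age-specific prostate-cancer mortality schedule, and post-cryotherapy
#' disease-free-survival data. These generators emulate each with simple,
#' clearly-synthetic structure so the full pipeline builds and tests
#' offline. The packaged default tables (under `extdata/`, filenames
#' prefixed `synthetic_`) are produced by these functions with the default
#' arguments.
#'
#' @name synthetic_data
NULL

#' Gompertz-Makeham parameters for the synthetic life table
#'
#' Annual hazard at age `x` is `c + a * exp(b * x)`. Defaults are calibrated
#' so the male period life expectancy at age 70 is about 13 years, the
#' UK-2010-like magnitude the model assumes.
#'
#' @param a Baseline Gompertz hazard (per year) at age 0.
#' @param b Log-slope per year of age.
#' @param c Makeham (age-independent) hazard per year.
#' @export
gompertz_params <- function(a = 2.1e-5, b = 0.102, c = 5e-4) {
  stopifnot(a > 0, b > 0, c >= 0)
  structure(list(a = a, b = b, c = c), class = "gompertz_params")
}

#' Generate a synthetic male life table
#'
#' `qx(age) = 1 - exp(-(c + a * exp(b * age)))`.
#'
#' @param gp A [gompertz_params()].
#' @param ages Integer ages covered by the table.
#' @return A [life_table()].
#' @export
generate_life_table <- function(gp = gompertz_params(), ages = 50:110) {
  stopifnot(inherits(gp, "gompertz_params"))
  qx <- 1 - exp(-(gp$c + gp$a * exp(gp$b * ages)))
  life_table(data.frame(age = as.integer(ages), qx = pmin(qx, 1)))
}

#' Generate a synthetic age-specific prostate-cancer mortality schedule
#'
#' Exponentially age-increasing annual death rate per person:
#' `rate(age) = rate_at_70 * exp(log_slope * (age - 70))`. In the model this
#' rate acts as the additional (excess) hazard of the Progression state.
#' The default magnitude is calibrated so the base-case model reproduces
#' the near-equality of life-years across treatment arms that the decision
#' problem exhibits (between-arm differences of roughly 0.04-0.05 years) —
#' the only anchor available for this schedule; see the methods vignette.
#'
#' @param ages Integer ages.
#' @param rate_at_70 Annual rate at age 70.
#' @param log_slope Exponential slope per year of age.
#' @return A [pc_mortality_table()].
#' @export
generate_pc_mortality <- function(ages = 50:110, rate_at_70 = 4e-4,
                                  log_slope = 0.07) {
  stopifnot(rate_at_70 >= 0)
  rate <- rate_at_70 * exp(log_slope * (ages - 70))
  pc_mortality_table(data.frame(age = as.integer(ages), rate = rate))
}

#' Discrete life expectancy at a given age
#'
#' Standard period life-table arithmetic on annual probabilities, with a
#' half-year correction for the year of death:
#' `e_x = sum_k prod_{j<k} (1 - q_{x+j}) - 0.5`.
#'
#' @param lt A [life_table()].
#' @param age Starting age (integer, within the table).
#' @export
life_expectancy <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  i <- match(age, lt$age)
  if (is.na(i)) stop("age not in table", call. = FALSE)
  q <- lt$qx[i:nrow(lt)]
  # extend with the last row until survivorship is negligible
  while (prod(1 - q) > 1e-8 && length(q) < 1000) q <- c(q, q[length(q)])
  sum(cumprod(1 - q)) + 0.5
}

#' Packaged synthetic mortality inputs
#'
#' Reads the versioned synthetic life table and prostate-cancer mortality
#' schedule shipped under `extdata/`.
#'
#' @param subtract_pc See [mortality_inputs()].
#' @export
default_mortality <- function(subtract_pc = FALSE) {
  lt <- read_life_table(system.file("extdata", "synthetic_male_lifetable.csv",
                                    package = "cryocea", mustWork = TRUE))
  pt <- read_pc_mortality(system.file("extdata", "synthetic_pc_mortality.csv",
                                      package = "cryocea", mustWork = TRUE))
  mortality_inputs(lt, pt, subtract_pc = subtract_pc)
}

#' Simulate Kaplan-Meier style disease-free-survival data from a spline model
#'
#' Event times are drawn by numerically inverting `S(t) = exp(-H(t))`
#' (bisection to 1e-8 months) using the monotone envelope of the model's
#' cumulative hazard — the running maximum, consistent with the engine's
#' floored hazard increments. Each subject is independently censored: with
#' probability `censoring_rate` at a uniform time on `(0, max_follow_up)`,
#' otherwise administratively at `max_follow_up`.
#'
#' @param model A [spline_model()] (or [weibull_model()]).
#' @param n Number of subjects.
#' @param censoring_rate Probability of random (non-administrative)
#'   censoring per subject.
#' @param max_follow_up Administrative censoring time (months).
#' @param seed Integer seed.
#' @return Data frame with columns `time_months`, `event`.
#' @export
simulate_km_dfs <- function(model, n, censoring_rate = 0, max_follow_up = 120,
                            seed) {
  stopifnot(n >= 1, censoring_rate >= 0, censoring_rate <= 1,
            max_follow_up > 0)
  set.seed(as.integer(seed))
  u <- stats::runif(n)
  cens_flag <- stats::runif(n) < censoring_rate
  cens_time <- ifelse(cens_flag, stats::runif(n) * max_follow_up,
                      max_follow_up)

  grid <- exp(seq(log(1e-6), log(max_follow_up), length.out = 512))
  H_env <- cummax(cumulative_hazard_any(model, grid))
  target <- -log(u)
  t_event <- rep(Inf, n)
  reachable <- target <= H_env[length(H_env)]
  inv <- function(ht) {
    lo_i <- findInterval(ht, H_env)  # H_env[lo_i] <= ht < H_env[lo_i+1]
    lo <- if (lo_i == 0) 1e-7 else grid[lo_i]
    hi <- if (lo_i >= length(grid)) max_follow_up else grid[lo_i + 1]
    while (hi - lo > 1e-8) {
      mid <- (lo + hi) / 2
      if (envelope_H(model, mid, grid, H_env) < ht) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  t_event[reachable] <- vapply(target[reachable], inv, numeric(1))
  obs <- pmin(t_event, cens_time)
  data.frame(time_months = obs, event = as.integer(t_event <= cens_time))
}

cumulative_hazard_any <- function(model, t) {
  if (inherits(model, "spline_model")) {
    cumulative_hazard(model, t)
  } else if (inherits(model, "weibull_model")) {
    (t / model$scale)^model$shape
  } else {
    stop("unsupported model class", call. = FALSE)
  }
}

# monotone envelope of H at an arbitrary point: H clipped below by the
# running maximum over the evaluation grid up to t
envelope_H <- function(model, t, grid, H_env) {
  i <- findInterval(t, grid)
  base <- if (i == 0) 0 else H_env[i]
  max(base, cumulative_hazard_any(model, t))
}
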