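test_that("rcs basis matches a brute-force evaluation of the cubic terms", {
  knots <- log(c(1, 24, 120))
  # independent oracle: evaluate the three plus-function cubes directly
  brute_s1 <- function(x) {
    lam <- (knots[3] - knots[2]) / (knots[3] - knots[1])
    cube <- function(u) if (u > 0) u^3 else 0
    cube(x - knots[2]) - lam * cube(x - knots[1]) -
      (1 - lam) * cube(x - knots[3])
  }
  xs <- c(-1, 0, 0.5, log(24), log(60), log(120), 5.5, 7)
  b <- rcs_basis(xs, knots)
  expect_equal(b[, "s0"], xs)
  expect_equal(b[, "s1"], vapply(xs, brute_s1, numeric(1)), tolerance = 1e-12)
  # below the lower boundary all plus-functions vanish
  expect_equal(unname(b[xs <= knots[1], "s1"]), c(0, 0))
})

test_that("s1 is linear beyond the boundary knots", {
  knots <- log(c(1, 24, 120))
  h <- 1e-3
  for (x0 in c(knots[3] + 0.2, knots[3] + 2, knots[1] - 0.5)) {
    s <- rcs_basis(c(x0 - h, x0, x0 + h), knots)[, "s1"]
    second_diff <- (s[1] - 2 * s[2] + s[3]) / h^2
    expect_lt(abs(second_diff), 1e-6)
  }
  expect_error(rcs_basis(1, log(c(24, 1, 120))), "strictly increasing")
})

test_that("the spline cumulative hazard has its closed-form special cases", {
  # gammas (0, 1, 0): H(t) = t (unit-rate exponential)
  m_exp <- spline_model(0, 1, 0, knots = log(c(1, 24, 120)))
  ts <- c(0.25, 1, 7, 60, 300)
  expect_equal(cumulative_hazard(m_exp, ts), ts, tolerance = 1e-12)
  # at t = 1 both bases vanish, so H = exp(gamma0)
  expect_equal(cumulative_hazard(base_spline(), 1), exp(-4.58))
  expect_error(cumulative_hazard(base_spline(), 0), "t must be > 0")
  # survival within (0, 1]
  S <- spline_survival(base_spline(), 1:432)
  expect_true(all(S > 0 & S <= 1))
})

test_that("monthly transition probabilities telescope to 1 - S(n)", {
  m <- monotone_spline()
  p <- monthly_transition_prob(m, 0:119)
  cum_recur <- 1 - cumprod(1 - p)
  expect_equal(cum_recur, 1 - spline_survival(m, 1:120), tolerance = 1e-12)
  # exponential: first cycle probability 1 - exp(-1)
  m_exp <- spline_model(0, 1, 0, knots = log(c(1, 24, 120)))
  expect_equal(monthly_transition_prob(m_exp, 0), 1 - exp(-1))
  expect_equal(monthly_transition_prob(m_exp, 5), 1 - exp(-1))
})

test_that("negative hazard increments are floored at zero", {
  # the base-case coefficients make H decline after ~6 months; probabilities
  # must still be valid and the implied survival nonincreasing
  p <- monthly_transition_prob(base_spline(), 0:431)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(any(p == 0))
  occ <- cumprod(1 - p)
  expect_true(all(diff(occ) <= 0))
})

test_that("maximum-likelihood fit recovers generating coefficients within 3 SEs", {
  # exponential special case, data-driven knots
  m_exp <- spline_model(0, 1, 0, knots = log(c(1, 24, 120)))
  km <- simulate_km_dfs(m_exp, n = 2000, censoring_rate = 0,
                        max_follow_up = 200, seed = 7)
  f <- fit_spline_km(km)
  expect_lt(abs(f$gamma[["gamma0"]] - 0) / f$se[["gamma0"]], 3)
  expect_lt(abs(f$gamma[["gamma1"]] - 1) / f$se[["gamma1"]], 3)
  expect_lt(abs(f$gamma[["gamma2"]] - 0) / f$se[["gamma2"]], 3)

  # full spline with 20% random censoring, fitted at the generating knots
  m <- monotone_spline()
  km2 <- simulate_km_dfs(m, n = 2000, censoring_rate = 0.2,
                         max_follow_up = 120, seed = 11)
  f2 <- fit_spline_km(km2, knots = m$knots)
  z <- abs(f2$gamma - m$gamma) / f2$se
  expect_true(all(z < 3))
})

test_that("fitting refuses datasets with too few events", {
  km <- data.frame(time_months = c(1:5, 10:30), event = c(rep(1, 5), rep(0, 21)))
  expect_error(fit_spline_km(km), "at least 10 events")
  expect_error(fit_spline_km(data.frame(time_months = c(-1, 2), event = c(1, 1))),
               "positive")
  expect_error(fit_spline_km(data.frame(time_months = c(1, 2), event = c(1, 2))),
               "0 or 1")
})

test_that("spline models and KM data round-trip through their file formats", {
  m <- spline_model(-4.58, 1.01, 0.303, knots = log(c(1, 24, 120)),
                    se = c(gamma0 = 0.408, gamma1 = 0.096, gamma2 = 0.068))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_spline_model(m, tmp)
  m2 <- read_spline_model(tmp)
  expect_equal(m2$gamma, m$gamma)
  expect_equal(m2$knots, m$knots)
  expect_equal(m2$se, m$se)

  km <- data.frame(time_months = c(1.5, 2, 8), event = c(1L, 0L, 1L))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_km_data(km, tmp2)
  expect_equal(read_km_data(tmp2), km)
})

test_that("weibull alternative model produces valid monthly probabilities", {
  w <- weibull_model(1.2, 60)
  p <- monthly_transition_prob(w, 0:119)
  expect_true(all(p >= 0 & p <= 1))
  # survival through 60 cycles telescopes to S(60) = exp(-(60/60)^1.2)
  expect_equal(cumprod(1 - p)[60], exp(-1), tolerance = 1e-9)
})
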