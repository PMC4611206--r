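# hand-built trace: one patient in BDFS-ADT for `months` cycles, then death
held_in_adt_trace <- function(months, horizon = months) {
  occ <- matrix(0, nrow = horizon + 1, ncol = 4,
                dimnames = list(NULL, c("pre_adt", "bdfs_adt", "progression",
                                        "death")))
  occ[, "death"] <- 1
  occ[seq_len(months), "bdfs_adt"] <- 1
  occ[seq_len(months), "death"] <- 0
  entries <- numeric(horizon + 1)
  entries[1] <- 1
  structure(list(occupancy = occ, age = 70 + (0:horizon) / 12,
                 adt_entries = entries, strategy = "ADT_IMMEDIATE"),
            class = "cohort_trace")
}

no_discount_draw <- function() {
  d <- point_draw()
  d$scalars$discount_rate_annual <- 0
  d
}

test_that("discount factors follow the annual rate in monthly cycles", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(12, 0.035), 1 / 1.035)
  expect_equal(discount_factor(12, 0.035), 0.96618, tolerance = 1e-5)
  expect_equal(discount_factor(432, 0.035), 1.035^-36)
  expect_equal(discount_factor(432, 0.035), 0.28983, tolerance = 1e-4)
  expect_equal(discount_factor(600, 0), 1)
  expect_error(discount_factor(12, -0.01))
})

test_that("a year held on first-line ADT costs the lead-in plus 11 maintenance cycles", {
  d <- no_discount_draw()
  sched <- state_cost_schedule(d)
  out <- accumulate(held_in_adt_trace(12), sched, state_utilities(d), d,
                    applies_sc_costs = FALSE, applies_ae = FALSE)
  expect_equal(out$cost, sched$adt_first_cycle + 11 * sched$adt_per_cycle,
               tolerance = 1e-12)
  expect_equal(out$ly, 1)
  # nothing accrues after death
  out2 <- accumulate(held_in_adt_trace(12, horizon = 48), sched,
                     state_utilities(d), d,
                     applies_sc_costs = FALSE, applies_ae = FALSE)
  expect_equal(out2$cost, out$cost)
  expect_equal(tail(out2$cum_cost, 1), out2$cost)
})

test_that("QALYs collapse to life-years with unit utilities and no discounting", {
  d <- no_discount_draw()
  sched <- state_cost_schedule(d)
  tr <- run_cohort(adt_deferred_strategy(), d, default_mortality())
  out <- accumulate(tr, sched, c(1, 1, 1, 0), d,
                    applies_sc_costs = FALSE, applies_ae = FALSE)
  expect_equal(out$qaly, out$ly, tolerance = 1e-12)
  # discounted QALYs never exceed life-years
  out2 <- accumulate(tr, sched, state_utilities(d), point_draw(),
                     applies_sc_costs = FALSE, applies_ae = FALSE)
  expect_lt(out2$qaly, out2$ly)
})

test_that("the cumulative trajectory is nondecreasing and ends at the total", {
  d <- point_draw()
  sched <- state_cost_schedule(d)
  mort <- default_mortality()
  for (s in default_strategies()) {
    out <- accumulate(run_cohort(s, d, mort), sched, state_utilities(d), d,
                      applies_sc_costs = s$applies_sc_costs,
                      applies_ae = s$applies_ae)
    expect_true(all(diff(out$cum_cost) >= -1e-12))
    expect_equal(tail(out$cum_cost, 1), out$cost)
    expect_gte(out$cost, 0)
  }
})

test_that("raising a unit cost weakly raises every strategy's total", {
  cfg <- base_config()
  cfg$unit_costs$goserelin <- cfg$unit_costs$goserelin + 50
  ps_hi <- build_parameter_set(cfg)
  mort <- default_mortality()
  res_lo <- run_base_case(base_ps(), mort = mort)
  res_hi <- run_base_case(ps_hi, mort = mort)
  for (id in names(res_lo$outcomes)) {
    expect_gte(res_hi$outcomes[[id]]$cost, res_lo$outcomes[[id]]$cost)
  }
})

test_that("adverse-event spreading preserves the undiscounted one-off total", {
  d <- no_discount_draw()
  sched <- state_cost_schedule(d)
  tr <- run_cohort(sc_strategy(), d, zero_mortality(), horizon = 12)
  spread <- accumulate(tr, sched, state_utilities(d), d)
  d0 <- no_discount_draw()
  d0$flags$ae_costs_at_cycle0 <- TRUE
  upfront <- accumulate(tr, sched, state_utilities(d0), d0)
  expect_equal(spread$cost, upfront$cost, tolerance = 1e-9)
})

test_that("incremental classification follows sign conventions", {
  mk <- function(id, cost, qaly) {
    structure(list(strategy = id, cost = cost, qaly = qaly, ly = qaly,
                   cum_cost = cost), class = "outcome_summary")
  }
  r <- incremental_analysis(mk("A", 100, 2), mk("B", 200, 1))
  expect_equal(r$classification, "dominant")
  r2 <- incremental_analysis(mk("A", 200, 1), mk("B", 100, 2))
  expect_equal(r2$classification, "dominated")
  r3 <- incremental_analysis(mk("A", 100 + 4291, 1 + 0.55), mk("B", 100, 1))
  expect_equal(r3$classification, "icer")
  expect_equal(r3$icer, 4291 / 0.55, tolerance = 1e-12)
  expect_equal(round(r3$icer), 7802)
  r4 <- incremental_analysis(mk("A", 100, 1), mk("B", 100, 1))
  expect_equal(r4$classification, "equivalent")
  r5 <- incremental_analysis(mk("A", 150, 1), mk("B", 100, 1))
  expect_equal(r5$classification, "undefined")
  expect_true(is.na(r5$icer))
})

test_that("cost-neutral time interpolates the first crossing", {
  mk <- function(cum) {
    structure(list(strategy = "X", cost = tail(cum, 1), qaly = 1, ly = 1,
                   cum_cost = cum), class = "outcome_summary")
  }
  # A pays 100 up front; B pays 10 per cycle: crossing at cycle 10
  a <- mk(rep(100, 24))
  b <- mk(cumsum(rep(10, 24)))
  expect_equal(cost_neutral_time(a, b), 10 / 12)
  # identical trajectories cross at time zero
  expect_equal(cost_neutral_time(a, a), 0)
  # B stays below A: no crossing
  b2 <- mk(cumsum(rep(1, 24)))
  expect_true(is.na(cost_neutral_time(a, b2)))
  # interpolation inside a cycle
  a3 <- mk(rep(15, 4))
  b3 <- mk(cumsum(rep(10, 4)))
  expect_equal(cost_neutral_time(a3, b3), 1.5 / 12)
})
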