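# Shared fixtures: everything is built in code at test time.

base_ps <- local({
  ps <- NULL
  function() {
    if (is.null(ps)) ps <<- default_parameter_set()
    ps
  }
})

base_config <- function() {
  jsonlite::read_json(system.file("extdata", "base_case.json",
                                  package = "cryocea", mustWork = TRUE),
                      simplifyVector = TRUE)
}

# parameter set with every standard error zeroed (degenerate draws)
zero_se_ps <- function() {
  cfg <- base_config()
  for (k in names(cfg$parameters)) cfg$parameters[[k]]$se <- 0
  build_parameter_set(cfg)
}

point_draw <- function(ps = base_ps()) draw_parameters(ps, point_estimate = TRUE)

flat_life_table <- function(qx, ages = 50:120) {
  life_table(data.frame(age = ages, qx = qx))
}

flat_pc_table <- function(rate, ages = 50:120) {
  pc_mortality_table(data.frame(age = ages, rate = rate))
}

zero_mortality <- function() {
  mortality_inputs(flat_life_table(0), flat_pc_table(0))
}

all_death_mortality <- function() {
  mortality_inputs(flat_life_table(1), flat_pc_table(0))
}

base_spline <- function() {
  spline_model(-4.58, 1.01, 0.303, knots = log(c(1, 24, 120)))
}

# a proper (monotone log-cumulative-hazard) spline under the packaged knots,
# used as the generating model for fit-recovery properties
monotone_spline <- function() {
  spline_model(-4.58, 1.01, -0.303, knots = log(c(1, 24, 120)))
}
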