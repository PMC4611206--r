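#' Life tables and prostate-cancer mortality schedules
#'
#' Background (all-cause) mortality enters every alive state as an annual
#' death probability `qx` converted to monthly scale; prostate-cancer
#' mortality enters the Progression state as an additional annual rate.
#' Ages beyond the last tabulated row reuse the last row.
#'
#' @param data Data frame with columns `age` (integer years) and `qx`
#'   (annual death probability in `[0, 1]`) for [life_table()], or `age` and
#'   `rate` (annual deaths per person, >= 0) for [pc_mortality_table()].
#' @return A validated data frame of class `life_table` /
#'   `pc_mortality_table`.
#' @export
life_table <- function(data) {
  data <- as.data.frame(data)
  check_age_table(data, "qx")
  if (any(data$qx < 0 | data$qx > 1)) {
    stop("life_table: qx must lie in [0,1]", call. = FALSE)
  }
  class(data) <- c("life_table", "data.frame")
  data
}

#' @rdname life_table
#' @export
pc_mortality_table <- function(data) {
  data <- as.data.frame(data)
  check_age_table(data, "rate")
  if (any(data$rate < 0)) {
    stop("pc_mortality_table: rates must be >= 0", call. = FALSE)
  }
  class(data) <- c("pc_mortality_table", "data.frame")
  data
}

check_age_table <- function(data, value_col) {
  req <- c("age", value_col)
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("table must have columns ", paste(req, collapse = ","),
         "; missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) < 1L) stop("table is empty", call. = FALSE)
  if (any(data$age != round(data$age))) {
    stop("table ages must be integers", call. = FALSE)
  }
  if (any(diff(data$age) != 1)) {
    stop("table ages must be contiguous and increasing", call. = FALSE)
  }
  invisible(data)
}

#' Read and write mortality tables as CSV
#'
#' Schemas: `age,qx` for life tables and `age,rate` for prostate-cancer
#' mortality. `write_*` followed by `read_*` is an identity.
#'
#' @param path CSV path.
#' @param lt,pt Tables created by [life_table()] / [pc_mortality_table()].
#' @export
read_life_table <- function(path) life_table(utils::read.csv(path))

#' @rdname read_life_table
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt)[c("age", "qx")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_life_table
#' @export
read_pc_mortality <- function(path) pc_mortality_table(utils::read.csv(path))

#' @rdname read_life_table
#' @export
write_pc_mortality <- function(pt, path) {
  stopifnot(inherits(pt, "pc_mortality_table"))
  utils::write.csv(as.data.frame(pt)[c("age", "rate")], path, row.names = FALSE)
  invisible(path)
}

lookup_age_value <- function(tab, value_col, age) {
  first <- tab$age[1]
  if (any(age < first)) {
    stop("age ", min(age), " below first table age ", first, call. = FALSE)
  }
  idx <- pmin(floor(age) - first + 1, nrow(tab))
  tab[[value_col]][idx]
}

#' Monthly background death probability from an annual life table
#'
#' Converts the annual probability of the completed age year by constant
#' hazard within the year: `q_m = 1 - (1 - qx)^(1/12)`, so that
#' `(1 - q_m)^12 = 1 - qx` exactly.
#'
#' @param lt A [life_table()].
#' @param age Age in (possibly fractional) years; vectorised.
#' @return Monthly death probability.
#' @export
monthly_death_prob <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  qx <- lookup_age_value(lt, "qx", age)
  1 - (1 - qx)^(1 / 12)
}

#' Monthly prostate-cancer excess death probability from an annual rate
#'
#' `q = 1 - exp(-rate / 12)`.
#'
#' @param pt A [pc_mortality_table()].
#' @param age Age in years; vectorised.
#' @export
monthly_pc_excess_hazard <- function(pt, age) {
  stopifnot(inherits(pt, "pc_mortality_table"))
  r <- lookup_age_value(pt, "rate", age)
  1 - exp(-r / 12)
}

#' Combine two within-cycle death probabilities
#'
#' Independent competing risks within a cycle:
#' `1 - (1 - q1) * (1 - q2)`.
#'
#' @param q1,q2 Monthly probabilities.
#' @export
combine_monthly_probs <- function(q1, q2) 1 - (1 - q1) * (1 - q2)

#' Bundle of mortality inputs for the engine
#'
#' When `subtract_pc` is `TRUE` the prostate-cancer hazard is removed from
#' the all-cause annual hazard before conversion, to avoid double counting
#' in the Progression state (off by default).
#'
#' @param lt A [life_table()].
#' @param pt A [pc_mortality_table()].
#' @param subtract_pc Subtract the prostate-cancer rate from the background
#'   hazard.
#' @return Object of class `mortality_inputs`.
#' @export
mortality_inputs <- function(lt, pt, subtract_pc = FALSE) {
  stopifnot(inherits(lt, "life_table"), inherits(pt, "pc_mortality_table"))
  if (subtract_pc) {
    rate <- lookup_age_value(pt, "rate", pmax(lt$age, pt$age[1]))
    h_bg <- pmax(-log(1 - lt$qx) - rate, 0)
    lt <- life_table(data.frame(age = lt$age, qx = 1 - exp(-h_bg)))
  }
  structure(list(life_table = lt, pc_table = pt), class = "mortality_inputs")
}
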