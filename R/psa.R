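#' Probabilistic sensitivity analysis
#'
#' Repeated Monte-Carlo parameter draws propagated through the full model.
#' One draw is shared by all strategy arms within an iteration (common
#' random numbers), so incremental results difference out shared parameter
#' uncertainty. Iteration `i` uses the sub-stream seed derived from
#' `seed` and `i`, making results reproducible bit-for-bit.
#'
#' @param ps A [build_parameter_set()] result.
#' @param strategies List of strategies (default [default_strategies()]).
#' @param n_iter Number of iterations (the source analysis used 10,000).
#' @param seed Integer base seed.
#' @param mort A [mortality_inputs()] bundle (default: packaged synthetic
#'   tables).
#' @return Object of class `psa_results`: data frame `draws` with columns
#'   `iteration`, `strategy`, `cost`, `qaly`, `ly`, plus `seed` and
#'   `n_iter`.
#' @export
run_psa <- function(ps, strategies = default_strategies(), n_iter, seed,
                    mort = default_mortality()) {
  stopifnot(n_iter >= 1)
  ids <- vapply(strategies, `[[`, character(1), "id")
  out <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    draw <- draw_parameters(ps, seed = substream_seed(seed, paste0("iter", i)))
    sched <- state_cost_schedule(draw)
    utils_ <- state_utilities(draw)
    res <- lapply(strategies, function(s) {
      accumulate(run_cohort(s, draw, mort), sched, utils_, draw,
                 applies_sc_costs = s$applies_sc_costs,
                 applies_ae = s$applies_ae)
    })
    out[[i]] <- data.frame(
      iteration = i, strategy = ids,
      cost = vapply(res, `[[`, numeric(1), "cost"),
      qaly = vapply(res, `[[`, numeric(1), "qaly"),
      ly = vapply(res, `[[`, numeric(1), "ly"))
  }
  structure(list(draws = do.call(rbind, out), seed = seed, n_iter = n_iter,
                 strategies = ids),
            class = "psa_results")
}

#' @export
print.psa_results <- function(x, ...) {
  cat(sprintf("<psa_results: %d iterations, seed %d, strategies %s>\n",
              x$n_iter, x$seed, paste(x$strategies, collapse = ", ")))
  agg <- stats::aggregate(cbind(cost, qaly) ~ strategy, x$draws, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness plane points
#'
#' Per-iteration incremental pairs, computed as comparator minus reference
#' (`comp - ref`), so a cheaper, more effective `comp` plots in the
#' south-east quadrant.
#'
#' @param r A [run_psa()] result.
#' @param ref,comp Strategy ids.
#' @return Data frame `iteration`, `delta_cost`, `delta_qaly`.
#' @export
ce_plane <- function(r, ref = "ADT_20DEF", comp = "SC") {
  stopifnot(inherits(r, "psa_results"), ref %in% r$strategies,
            comp %in% r$strategies)
  d <- r$draws
  a <- d[d$strategy == comp, ]; b <- d[d$strategy == ref, ]
  a <- a[order(a$iteration), ]; b <- b[order(b$iteration), ]
  data.frame(iteration = a$iteration,
             delta_cost = a$cost - b$cost,
             delta_qaly = a$qaly - b$qaly)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability (across PSA
#' iterations) that each strategy maximises net monetary benefit
#' `lambda * QALY - cost`. Ties are split equally. The default grid covers
#' 0 to 50,000 GBP/QALY in steps of 500, spanning the 20,000-30,000
#' decision band.
#'
#' @param r A [run_psa()] result.
#' @param wtp_grid Thresholds in GBP per QALY.
#' @return Object of class `ceac_curve`: data frame `wtp`, `strategy`,
#'   `probability`.
#' @export
ceac <- function(r, wtp_grid = seq(0, 50000, by = 500)) {
  stopifnot(inherits(r, "psa_results"), length(wtp_grid) >= 1)
  d <- r$draws
  ids <- r$strategies
  cost <- matrix(NA_real_, r$n_iter, length(ids), dimnames = list(NULL, ids))
  qaly <- cost
  for (s in ids) {
    sub <- d[d$strategy == s, ]
    sub <- sub[order(sub$iteration), ]
    cost[, s] <- sub$cost
    qaly[, s] <- sub$qaly
  }
  rows <- lapply(wtp_grid, function(lambda) {
    nmb <- lambda * qaly - cost
    best <- nmb == apply(nmb, 1, max)
    win <- best / rowSums(best)  # split ties equally
    data.frame(wtp = lambda, strategy = ids, probability = colMeans(win),
               row.names = NULL)
  })
  structure(do.call(rbind, rows), class = c("ceac_curve", "data.frame"))
}

#' @rdname ceac
#' @param threshold A single willingness-to-pay threshold.
#' @param strategy Strategy id.
#' @export
prob_cost_effective <- function(r, threshold, strategy = "SC") {
  cv <- ceac(r, wtp_grid = threshold)
  cv$probability[cv$strategy == strategy]
}
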