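#' Uncertainty distributions specified by mean and standard error
#'
#' Every probabilistic quantity in the model is specified in the source
#' tables by a point estimate, a standard error and a distribution family
#' (beta for probabilities and utilities, gamma for costs and resource use,
#' log-normal for the relative risk, normal for spline coefficients).
#' `dist_spec()` captures one such specification; the `*_from_mean_se()`
#' helpers convert it to the family's natural parameters by the method of
#' moments.
#'
#' @param family One of `"fixed"`, `"beta"`, `"gamma"`, `"normal"`,
#'   `"lognormal"`.
#' @param mean Point estimate (the distribution's natural-scale mean).
#' @param se Standard error (natural-scale standard deviation); `0` gives a
#'   degenerate draw for any family.
#' @param name Optional parameter name used in validation messages.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("beta", 0.4, 0.08)
#' dist_spec("fixed", 65)
#' @export
dist_spec <- function(family, mean, se = 0, name = NULL) {
  family <- match.arg(family, c("fixed", "beta", "gamma", "normal", "lognormal"))
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(se), length(se) == 1L, is.finite(se))
  if (se < 0) {
    stop("dist_spec", label_for(name), ": se must be >= 0", call. = FALSE)
  }
  if (se > 0) {
    # parameter feasibility is checked eagerly so config errors surface early
    switch(family,
      beta = beta_from_mean_se(mean, se, name = name),
      gamma = gamma_from_mean_se(mean, se, name = name),
      lognormal = lognormal_from_mean_se(mean, se, name = name),
      NULL)
  } else if (family == "beta" && (mean <= 0 || mean >= 1)) {
    stop("dist_spec", label_for(name), ": beta mean must lie strictly in (0,1)",
         call. = FALSE)
  } else if (family %in% c("gamma", "lognormal") && mean < 0) {
    # se = 0 gives a degenerate draw, so a zero mean is admissible here
    stop("dist_spec", label_for(name), ": ", family, " mean must be >= 0",
         call. = FALSE)
  }
  structure(list(family = family, mean = mean, se = se, name = name),
            class = "dist_spec")
}

label_for <- function(name) if (is.null(name)) "" else paste0(" '", name, "'")

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec %s: mean %.6g, se %.6g>\n", x$family, x$mean, x$se))
  invisible(x)
}

#' Beta shape parameters from a mean and standard error
#'
#' Method-of-moments inversion: with `n = mean * (1 - mean) / se^2 - 1`,
#' `alpha = mean * n` and `beta = (1 - mean) * n`, so the analytic mean and
#' standard deviation of `Beta(alpha, beta)` equal the inputs.
#'
#' @param mean Mean, strictly in (0, 1).
#' @param se Standard error; must satisfy `se^2 < mean * (1 - mean)`.
#' @param name Optional parameter name for error messages.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' beta_from_mean_se(0.4, 0.08)   # c(alpha = 14.6, beta = 21.9)
#' @export
beta_from_mean_se <- function(mean, se, name = NULL) {
  if (!(mean > 0 && mean < 1)) {
    stop("beta parameter", label_for(name), ": mean must lie strictly in (0,1), got ",
         mean, call. = FALSE)
  }
  if (se <= 0 || se^2 >= mean * (1 - mean)) {
    stop("beta parameter", label_for(name), ": need 0 < se^2 < mean*(1-mean); got se = ",
         se, " with mean = ", mean, call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Gamma shape and scale from a mean and standard error
#'
#' `shape = (mean/se)^2`, `scale = se^2/mean`; the analytic mean and SD of
#' `Gamma(shape, scale)` equal the inputs.
#'
#' @inheritParams beta_from_mean_se
#' @return Named numeric vector `c(shape, scale)`.
#' @examples
#' gamma_from_mean_se(2170, 434)  # c(shape = 25, scale = 86.8)
#' @export
gamma_from_mean_se <- function(mean, se, name = NULL) {
  if (mean <= 0 || se <= 0) {
    stop("gamma parameter", label_for(name),
         ": mean and se must be > 0; got mean = ", mean, ", se = ", se,
         call. = FALSE)
  }
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Log-normal parameters from a natural-scale mean and standard error
#'
#' Parameterised so that the natural-scale mean and SD of the log-normal
#' equal the inputs: `sigma^2 = log(1 + (se/mean)^2)`,
#' `mu = log(mean) - sigma^2/2`. An `se` of zero returns the degenerate
#' `c(log(mean), 0)`.
#'
#' @inheritParams beta_from_mean_se
#' @return Named numeric vector `c(mu, sigma)` (log-scale parameters).
#' @examples
#' lognormal_from_mean_se(1.5, 1.38)
#' @export
lognormal_from_mean_se <- function(mean, se, name = NULL) {
  if (mean <= 0 || se < 0) {
    stop("lognormal parameter", label_for(name),
         ": need mean > 0 and se >= 0; got mean = ", mean, ", se = ", se,
         call. = FALSE)
  }
  sigma2 <- log(1 + (se / mean)^2)
  c(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Draw one realisation from a `dist_spec`
#'
#' Fixed specs (or any spec with `se = 0`) return the mean unchanged.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$family == "fixed" || spec$se == 0) {
    return(rep(spec$mean, n))
  }
  switch(spec$family,
    beta = {
      p <- beta_from_mean_se(spec$mean, spec$se, spec$name)
      stats::rbeta(n, p[["alpha"]], p[["beta"]])
    },
    gamma = {
      p <- gamma_from_mean_se(spec$mean, spec$se, spec$name)
      stats::rgamma(n, shape = p[["shape"]], scale = p[["scale"]])
    },
    normal = stats::rnorm(n, spec$mean, spec$se),
    lognormal = {
      p <- lognormal_from_mean_se(spec$mean, spec$se, spec$name)
      stats::rlnorm(n, p[["mu"]], p[["sigma"]])
    })
}
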