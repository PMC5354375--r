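#' Paired wild-type / knock-out data for one gene pair
#'
#' Container for the expression values of a candidate gene X and the
#' knocked-out gene G across wild-type (observational) and knock-out
#' (interventional) samples. In the KO samples G is not observed freely: it
#' is clamped to `do_value` by the intervention, so only X is recorded there.
#'
#' @param wt_g Numeric vector, expression of the knocked-out gene G in the
#'   wild-type samples.
#' @param wt_x Numeric vector, expression of the candidate gene X in the same
#'   wild-type samples (same length and order as `wt_g`).
#' @param ko_x Numeric vector, expression of X in the knock-out samples. May
#'   be empty: purely observational data is legal (and renders the two models
#'   indistinguishable).
#' @param do_value Scalar, the value G is clamped to under the intervention
#'   do(G = g). Knock-outs are conventionally modelled as clamping expression
#'   to (a value close to) zero, hence the default.
#'
#' @return An object of class `intervention_data`.
#' @seealso [fit_m1()], [fit_m0()], [bayes_factor()], [simulate_pair()]
#' @export
intervention_data <- function(wt_g, wt_x, ko_x = numeric(0), do_value = 0) {
  wt_g <- as.numeric(wt_g)
  wt_x <- as.numeric(wt_x)
  ko_x <- as.numeric(ko_x)
  if (length(wt_g) != length(wt_x)) {
    stop("wt_g and wt_x must have the same length (paired WT samples)")
  }
  if (!all(is.finite(wt_g)) || !all(is.finite(wt_x)) || !all(is.finite(ko_x))) {
    stop("expression values must all be finite")
  }
  if (!is.numeric(do_value) || length(do_value) != 1L || !is.finite(do_value)) {
    stop("do_value must be a single finite number")
  }
  structure(
    list(wt_g = wt_g, wt_x = wt_x, ko_x = ko_x, do_value = do_value),
    class = "intervention_data"
  )
}

#' @export
print.intervention_data <- function(x, ...) {
  cat(sprintf(
    "<intervention_data> %d WT pairs, %d KO samples, do_value = %g\n",
    length(x$wt_g), length(x$ko_x), x$do_value
  ))
  invisible(x)
}

#' Downstream-model parameter set
#'
#' The shared 5-parameter set used by both competing models: under the
#' downstream model M1 the candidate gene X responds linearly to the
#' knocked-out gene G, `X = mu_x + alpha * G + eps`, with
#' `G ~ N(mu_g, sigma_g^2)` and `eps ~ N(0, sigma_x^2)`. The upstream and
#' correlated alternatives are Markov-equivalent to this form on
#' observational data, so the same parameter set also carries the pooled
#' alternative model M0.
#'
#' @param mu_g Mean of G.
#' @param sigma_g Residual standard deviation of G (> 0).
#' @param mu_x Residual mean (intercept) of X.
#' @param sigma_x Residual standard deviation of X (> 0).
#' @param alpha Total causal effect of G on X.
#'
#' @return An object of class `downstream_params`.
#' @seealso [as_bivariate()], [as_downstream()]
#' @export
downstream_params <- function(mu_g, sigma_g, mu_x, sigma_x, alpha) {
  vals <- c(mu_g = mu_g, sigma_g = sigma_g, mu_x = mu_x,
            sigma_x = sigma_x, alpha = alpha)
  if (!all(is.finite(vals))) stop("all parameters must be finite")
  if (sigma_g <= 0) stop("sigma_g must be > 0")
  if (sigma_x <= 0) stop("sigma_x must be > 0")
  structure(as.list(vals), class = "downstream_params")
}

#' @export
print.downstream_params <- function(x, ...) {
  cat(sprintf(
    "<downstream_params> mu_g = %g, sigma_g = %g, mu_x = %g, sigma_x = %g, alpha = %g\n",
    x$mu_g, x$sigma_g, x$mu_x, x$sigma_x, x$alpha
  ))
  invisible(x)
}

#' Bivariate-correlated parameter set
#'
#' Parameters of the bivariate Gaussian law of (G, X) used by the correlated
#' form of the alternative model: means `m1`, `m2`, standard deviations
#' `s1`, `s2` and correlation `rho`. Exactly convertible to and from the
#' downstream parameterization (see [as_downstream()] / [as_bivariate()]).
#'
#' @param m1 Mean of G.
#' @param m2 Mean of X.
#' @param s1 Standard deviation of G (> 0).
#' @param s2 Standard deviation of X (> 0).
#' @param rho Correlation between G and X, in \[-1, 1\].
#'
#' @return An object of class `bivariate_params`.
#' @export
bivariate_params <- function(m1, m2, s1, s2, rho) {
  vals <- c(m1 = m1, m2 = m2, s1 = s1, s2 = s2, rho = rho)
  if (!all(is.finite(vals))) stop("all parameters must be finite")
  if (s1 <= 0) stop("s1 must be > 0")
  if (s2 <= 0) stop("s2 must be > 0")
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  structure(as.list(vals), class = "bivariate_params")
}

#' @export
print.bivariate_params <- function(x, ...) {
  cat(sprintf(
    "<bivariate_params> m1 = %g, m2 = %g, s1 = %g, s2 = %g, rho = %g\n",
    x$m1, x$m2, x$s1, x$s2, x$rho
  ))
  invisible(x)
}

#' Convert bivariate-correlated parameters to the downstream form
#'
#' Reparameterizes the bivariate Gaussian law of (G, X) as a downstream
#' structural equation `X = mu_x + alpha G + eps`: the regression-based
#' identities `alpha = rho * s2 / s1`, `mu_x = m2 - alpha * m1`,
#' `sigma_x = sqrt(s2^2 - alpha^2 * s1^2)`, with G keeping its marginal
#' (`mu_g = m1`, `sigma_g = s1`). The map is an exact bijection for
#' `|rho| < 1`; at `|rho| = 1` the residual variance of X degenerates to
#' zero and an error is raised.
#'
#' @param b A [bivariate_params()] object.
#' @return A [downstream_params()] object.
#' @export
as_downstream <- function(b) {
  stopifnot(inherits(b, "bivariate_params"))
  if (abs(b$rho) >= 1) {
    stop("|rho| = 1 is degenerate: residual sd of X would be zero")
  }
  alpha <- b$rho * b$s2 / b$s1
  downstream_params(
    mu_g = b$m1,
    sigma_g = b$s1,
    mu_x = b$m2 - alpha * b$m1,
    sigma_x = sqrt(b$s2^2 - alpha^2 * b$s1^2),
    alpha = alpha
  )
}

#' Convert downstream parameters to the implied bivariate Gaussian
#'
#' Inverse of [as_downstream()]: the observational joint law of (G, X) under
#' the downstream model is bivariate Gaussian with `m1 = mu_g`, `s1 =
#' sigma_g`, `m2 = mu_x + alpha * mu_g`, `s2 = sqrt(alpha^2 sigma_g^2 +
#' sigma_x^2)` and `rho = alpha * s1 / s2`.
#'
#' @param theta A [downstream_params()] object.
#' @return A [bivariate_params()] object.
#' @export
as_bivariate <- function(theta) {
  stopifnot(inherits(theta, "downstream_params"))
  s2 <- sqrt(theta$alpha^2 * theta$sigma_g^2 + theta$sigma_x^2)
  bivariate_params(
    m1 = theta$mu_g,
    m2 = theta$mu_x + theta$alpha * theta$mu_g,
    s1 = theta$sigma_g,
    s2 = s2,
    rho = theta$alpha * theta$sigma_g / s2
  )
}

#' Convert bivariate-correlated parameters to the upstream form
#'
#' Symmetric counterpart of [as_downstream()] with the roles of G and X
#' swapped: `G = mu2_tilde + beta * X + eps` with `beta = rho * s1 / s2` and
#' residual sd `sqrt(s1^2 - beta^2 * s2^2)`. Provided for completeness and
#' for testing the G/X symmetry; the alternative model is always fit in the
#' downstream parameterization.
#'
#' @param b A [bivariate_params()] object.
#' @return A named list with elements `mu1` (mean of X), `mu2` (residual
#'   mean of G), `sigma1` (sd of X), `sigma2` (residual sd of G) and `beta`
#'   (regression coefficient of G on X).
#' @export
as_upstream <- function(b) {
  stopifnot(inherits(b, "bivariate_params"))
  if (abs(b$rho) >= 1) {
    stop("|rho| = 1 is degenerate: residual sd of G would be zero")
  }
  beta <- b$rho * b$s1 / b$s2
  list(
    mu1 = b$m2,
    mu2 = b$m1 - beta * b$m2,
    sigma1 = b$s2,
    sigma2 = sqrt(b$s1^2 - beta^2 * b$s2^2),
    beta = beta
  )
}
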