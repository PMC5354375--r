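#' Log-likelihood components of the two marginal causal models
#'
#' Both competing models share the wild-type (observational) term and differ
#' only in how the knock-out samples of the candidate gene X are modelled:
#'
#' * `loglik_wt()`: the observational term, summing the conditional density
#'   of X given G and the marginal density of G over all WT pairs.
#' * `loglik_ko_m1()`: the downstream-model KO term. Under do(G = g) a
#'   downstream X responds, so each KO value is scored against
#'   `N(mu_x + alpha * do_value, sigma_x^2)`.
#' * `loglik_ko_m0()`: the pooled upstream/correlated KO term. An upstream
#'   or merely correlated X is unaffected by the intervention and keeps its
#'   observational marginal `N(mu_x + alpha * mu_g, alpha^2 sigma_g^2 +
#'   sigma_x^2)`; the term does not involve `do_value`.
#' * `loglik_m1()` and `loglik_m0()`: the full model log-likelihoods,
#'   `loglik_wt + loglik_ko_m1` and `loglik_wt + loglik_ko_m0`.
#'
#' All are exact sums over samples; KO terms are zero for an empty KO set,
#' so `loglik_m1()` and `loglik_m0()` agree exactly on purely observational
#' data (the Markov equivalence that makes intervention data necessary).
#'
#' @param theta A [downstream_params()] object.
#' @param data An [intervention_data()] object.
#' @return A single log-likelihood value.
#' @name loglik
NULL

check_theta <- function(theta) {
  if (!inherits(theta, "downstream_params")) {
    # tolerate plain lists with the right fields (used by the optimizer)
    required <- c("mu_g", "sigma_g", "mu_x", "sigma_x", "alpha")
    if (!is.list(theta) || !all(required %in% names(theta))) {
      stop("theta must be a downstream_params object")
    }
  }
  if (theta$sigma_g <= 0 || theta$sigma_x <= 0) {
    stop("standard deviations must be > 0")
  }
  invisible(theta)
}

#' @rdname loglik
#' @export
loglik_wt <- function(theta, data) {
  check_theta(theta)
  stopifnot(inherits(data, "intervention_data"))
  if (length(data$wt_g) == 0L) {
    stop("no WT samples: model is unidentifiable without observational data")
  }
  sum(stats::dnorm(data$wt_x, theta$mu_x + theta$alpha * data$wt_g,
                   theta$sigma_x, log = TRUE)) +
    sum(stats::dnorm(data$wt_g, theta$mu_g, theta$sigma_g, log = TRUE))
}

#' @rdname loglik
#' @export
loglik_ko_m1 <- function(theta, data) {
  check_theta(theta)
  stopifnot(inherits(data, "intervention_data"))
  if (length(data$ko_x) == 0L) return(0)
  sum(stats::dnorm(data$ko_x, theta$mu_x + theta$alpha * data$do_value,
                   theta$sigma_x, log = TRUE))
}

#' @rdname loglik
#' @export
loglik_ko_m0 <- function(theta, data) {
  check_theta(theta)
  stopifnot(inherits(data, "intervention_data"))
  if (length(data$ko_x) == 0L) return(0)
  marg_sd <- sqrt(theta$alpha^2 * theta$sigma_g^2 + theta$sigma_x^2)
  sum(stats::dnorm(data$ko_x, theta$mu_x + theta$alpha * theta$mu_g,
                   marg_sd, log = TRUE))
}

#' @rdname loglik
#' @export
loglik_m1 <- function(theta, data) {
  loglik_wt(theta, data) + loglik_ko_m1(theta, data)
}

#' @rdname loglik
#' @export
loglik_m0 <- function(theta, data) {
  loglik_wt(theta, data) + loglik_ko_m0(theta, data)
}
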