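# Independent oracles and random-case generators shared across tests.

# log-density of the bivariate Gaussian, written out directly from the
# closed form (independent of the package's likelihood code)
bivariate_logdens <- function(g, x, m1, m2, s1, s2, rho) {
  z1 <- (g - m1) / s1
  z2 <- (x - m2) / s2
  q <- (z1^2 - 2 * rho * z1 * z2 + z2^2) / (1 - rho^2)
  -log(2 * pi * s1 * s2 * sqrt(1 - rho^2)) - q / 2
}

# brute-force total effect: enumerate every directed path from source to
# target and sum the products of edge weights along each path
path_sum_effect <- function(dag, source, target) {
  total <- 0
  walk <- function(node, prod) {
    out <- dag$edges[dag$edges$from == node, , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      p <- prod * out$weight[i]
      if (out$to[i] == target) total <<- total + p
      walk(out$to[i], p)
    }
  }
  walk(source, 1)
  total
}

# random DAG on n nodes: edges only from lower to higher index, so
# acyclicity holds by construction
random_dag <- function(n, edge_prob = 0.5) {
  nodes <- paste0("v", seq_len(n))
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (stats::runif(1) < edge_prob) {
        from <- c(from, nodes[i]); to <- c(to, nodes[j])
      }
    }
  }
  weighted_dag(
    nodes,
    data.frame(from = from, to = to,
               weight = stats::runif(length(from), -2, 2),
               stringsAsFactors = FALSE),
    intercepts = stats::rnorm(n),
    residual_sd = stats::runif(n, 0.1, 0.5)
  )
}

random_downstream_params <- function() {
  downstream_params(
    mu_g = stats::rnorm(1, 0, 2),
    sigma_g = stats::runif(1, 0.1, 2),
    mu_x = stats::rnorm(1, 0, 2),
    sigma_x = stats::runif(1, 0.1, 2),
    alpha = stats::rnorm(1, 0, 1.5)
  )
}

random_bivariate_params <- function() {
  bivariate_params(
    m1 = stats::rnorm(1, 0, 2), m2 = stats::rnorm(1, 0, 2),
    s1 = stats::runif(1, 0.1, 2), s2 = stats::runif(1, 0.1, 2),
    rho = stats::runif(1, -0.95, 0.95)
  )
}

random_dataset <- function(n_wt = 10, n_ko = 5) {
  intervention_data(
    wt_g = stats::rnorm(n_wt, 1, 0.5),
    wt_x = stats::rnorm(n_wt, 2, 0.7),
    ko_x = stats::rnorm(n_ko, 2, 0.7),
    do_value = 0
  )
}
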