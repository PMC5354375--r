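test_that("closed-form M1 fit recovers regression parameters exactly", {
  # three non-collinear points with known least-squares solution
  d <- intervention_data(wt_g = c(0, 1, 2), wt_x = c(0.1, 1, 2.1))
  fit <- fit_m1(d)
  lmfit <- stats::lm(d$wt_x ~ d$wt_g)
  expect_equal(fit$alpha, unname(coef(lmfit)[2]))
  expect_equal(fit$mu_x, unname(coef(lmfit)[1]))
  expect_equal(fit$sigma_x, sqrt(mean(residuals(lmfit)^2)))
  expect_equal(fit$mu_g, 1)
  expect_equal(fit$sigma_g, sqrt(mean((c(0, 1, 2) - 1)^2)))
})

test_that("M1 fit is consistent: alpha_hat converges to the true effect", {
  set.seed(51)
  theta <- downstream_params(1, 0.5, 0, 0.7, 2)
  d <- simulate_pair("M1", theta, n_wt = 1e4, n_ko = 1e4, do_value = 0)
  fit <- fit_m1(d)
  expect_lt(abs(fit$alpha - 2), 0.05)
  expect_lt(abs(fit$mu_g - 1), 0.05)

  # bias shrinks and spread scales like 1/sqrt(n) across the design sizes
  sds <- sapply(c(6, 12, 24, 48), function(n) {
    est <- replicate(60, {
      dd <- simulate_pair("M1", theta, n, n, 0)
      fit_m1(dd)$alpha
    })
    expect_lt(abs(mean(est) - 2), 0.2)
    sd(est)
  })
  expect_true(all(diff(sds) < 0))
})

test_that("M1 fit dominates the likelihood at random parameter values", {
  set.seed(52)
  d <- random_dataset(n_wt = 15, n_ko = 8)
  best <- loglik_m1(fit_m1(d), d)
  for (i in 1:100) {
    expect_gte(best, loglik_m1(random_downstream_params(), d))
  }
})

test_that("closed-form M1 fit agrees with a generic numeric maximizer", {
  set.seed(53)
  for (i in 1:50) {
    d <- random_dataset(n_wt = sample(5:20, 1), n_ko = sample(0:10, 1))
    closed <- loglik_m1(fit_m1(d), d)
    # independent route: direct numeric maximization of the M1 objective
    obj <- function(p) {
      th <- list(mu_g = p[1], sigma_g = exp(p[2]), mu_x = p[3],
                 sigma_x = exp(p[4]), alpha = p[5])
      ll <- tryCatch(loglik_m1(th, d), error = function(e) -Inf)
      if (!is.finite(ll)) return(1e300)
      -ll
    }
    opt <- stats::optim(c(0, 0, 0, 0, 0), obj, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    expect_lt(abs(closed + opt$value), 1e-6)
    expect_gte(closed + opt$value, -1e-6) # closed form is never beaten
  }
})

test_that("M1 fit rejects degenerate designs", {
  expect_error(fit_m1(intervention_data(wt_g = 1, wt_x = 1)), "at least 2")
  expect_error(fit_m1(intervention_data(wt_g = c(1, 1), wt_x = c(0, 2))),
               "degenerate design")
  # perfectly collinear points leave zero residual variance
  expect_error(fit_m1(intervention_data(wt_g = c(0, 1), wt_x = c(0, 1))),
               "jitter")
})

test_that("M0 fit equals the M1 fit when there is no interventional data", {
  set.seed(54)
  d <- random_dataset(n_wt = 20, n_ko = 0)
  f1 <- loglik_m1(fit_m1(d), d)
  f0 <- loglik_m0(fit_m0(d), d)
  expect_equal(f0, f1, tolerance = 1e-8)
})

test_that("M0 fit never falls below its starting points and recovers truth", {
  set.seed(55)
  b <- bivariate_params(1, 2, 0.5, 0.8, 0.6)
  d <- simulate_pair("M0", b, n_wt = 1e4, n_ko = 1e4, do_value = 0)

  init <- random_downstream_params()
  fit <- fit_m0(d, init = init)
  expect_gte(loglik_m0(fit, d), loglik_m0(init, d))
  expect_gte(loglik_m0(fit, d), loglik_m0(fit_m1(d), d))

  # the implied bivariate law should match the generating one
  bhat <- as_bivariate(fit)
  expect_equal(bhat$m1, b$m1, tolerance = 0.05)
  expect_equal(bhat$m2, b$m2, tolerance = 0.05)
  expect_equal(bhat$s1, b$s1, tolerance = 0.05)
  expect_equal(bhat$s2, b$s2, tolerance = 0.05)
  expect_equal(bhat$rho, b$rho, tolerance = 0.05)
})

test_that("Bayes factor is exactly the prior odds with no KO samples", {
  set.seed(56)
  for (i in 1:10) {
    d <- random_dataset(n_wt = 10, n_ko = 0)
    expect_identical(bayes_factor(d)$log10_bf, 0)
    expect_equal(bayes_factor(d, prior_odds = 10)$log10_bf, 1)
  }
})

test_that("Bayes factor separates downstream pairs from correlated pairs", {
  theta <- downstream_params(2, 0.09, 1, 0.15, 1)
  d1 <- simulate_pair("M1", theta, 24, 24, do_value = 0, seed = 57)
  expect_lt(bayes_factor(d1)$log10_bf, -5)
  expect_identical(bayes_factor(d1)$label, "downstream")

  d0 <- simulate_pair("M0", as_bivariate(theta), 24, 24, do_value = 0,
                      seed = 58)
  expect_gt(bayes_factor(d0)$log10_bf, -0.5)
  expect_identical(bayes_factor(d0)$label, "not_downstream")
})

test_that("Bayes factor is invariant to affine rescaling of both genes", {
  set.seed(59)
  theta <- downstream_params(2, 0.3, 1, 0.5, 1)
  for (i in 1:5) {
    d <- simulate_pair("M1", theta, 24, 24, do_value = 0)
    a <- runif(1, 0.5, 3) * sample(c(-1, 1), 1)
    b <- rnorm(1)
    cc <- runif(1, 0.5, 3) * sample(c(-1, 1), 1)
    dd <- rnorm(1)
    d_scaled <- intervention_data(
      wt_g = cc * d$wt_g + dd, wt_x = a * d$wt_x + b,
      ko_x = a * d$ko_x + b, do_value = cc * d$do_value + dd
    )
    expect_equal(bayes_factor(d_scaled)$log10_bf, bayes_factor(d)$log10_bf,
                 tolerance = 1e-6)
  }
})

test_that("evidence for the downstream model accumulates with KO samples", {
  set.seed(60)
  theta <- downstream_params(2, 0.3, 1, 0.5, 1)
  mean_bf <- sapply(c(2, 8, 24), function(n_ko) {
    mean(replicate(100, {
      d <- simulate_pair("M1", theta, 24, n_ko, do_value = 0)
      bayes_factor(d)$log10_bf
    }))
  })
  expect_true(all(diff(mean_bf) < 0))
})

test_that("gene screening reports every candidate gene and flags failures", {
  set.seed(61)
  expr <- rbind(
    ko = rnorm(8, 2, 0.3),
    a = rnorm(8, 1, 0.4),
    flat = rep(1, 8),
    b = rnorm(8, 0, 0.5)
  )
  colnames(expr) <- paste0("s", 1:8)
  cond <- rep(c("WT", "KO"), each = 4)
  expr["ko", cond == "KO"] <- 0

  res <- screen_genes(expr, "ko", cond)
  expect_identical(nrow(res), nrow(expr) - 1L)
  expect_identical(res$gene_id, c("a", "flat", "b"))
  expect_identical(res$status[res$gene_id == "flat"] == "ok", FALSE)
  expect_true(is.na(res$log10_bf[res$gene_id == "flat"]))
  expect_true(all(res$status[res$gene_id != "flat"] == "ok"))

  expect_error(screen_genes(expr, "absent", cond), "not found")
  expect_error(screen_genes(expr, "ko", rep("treated", 8)), "WT")
  expect_error(screen_genes(expr, "ko", cond[-1]), "one label per sample")
})
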