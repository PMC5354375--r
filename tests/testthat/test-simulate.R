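test_that("simulation is bit-identical under the same seed", {
  dag <- benchmark_dag()
  s1 <- simulate_dag(dag, 10, 10, "g6", 0, seed = 71)
  s2 <- simulate_dag(dag, 10, 10, "g6", 0, seed = 71)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$condition, s2$condition)

  theta <- downstream_params(1, 0.2, 0, 0.3, 1.5)
  p1 <- simulate_pair("M1", theta, 12, 12, 0, seed = 72)
  p2 <- simulate_pair("M1", theta, 12, 12, 0, seed = 72)
  expect_identical(p1, p2)
})

test_that("do-semantics: the intervened node is clamped and its inputs severed", {
  dag <- benchmark_dag()
  sim <- simulate_dag(dag, 5, 7, "g6", do_value = -3, seed = 73)
  ko_cols <- sim$condition == "KO"
  expect_true(all(sim$expr["g6", ko_cols] == -3))
  expect_false(any(sim$expr["g6", !ko_cols] == -3))

  # noiseless chain: with do(A = 0) the child keeps only its intercept
  chain <- weighted_dag(c("A", "B"),
                        data.frame(from = "A", to = "B", weight = 2),
                        intercepts = c(A = 1, B = 5),
                        residual_sd = c(A = 0, B = 0))
  sim2 <- simulate_dag(chain, 3, 4, "A", do_value = 0, seed = 74)
  ko <- sim2$condition == "KO"
  expect_true(all(sim2$expr["B", ko] == 5))
  expect_true(all(sim2$expr["B", !ko] == 5 + 2 * 1))
})

test_that("nodes unaffected by the intervention keep their observational law", {
  dag <- benchmark_dag()
  sim <- simulate_dag(dag, 5000, 5000, "g6", 0, seed = 75)
  wt <- sim$condition == "WT"
  tt <- truth_table(dag, "g6")
  null_genes <- tt$gene_id[!tt$downstream]
  pvals <- sapply(null_genes, function(g) {
    stats::ks.test(sim$expr[g, wt], sim$expr[g, !wt])$p.value
  })
  expect_true(all(pvals > 0.01 / length(null_genes)))
})

test_that("KO means of downstream nodes match the intercept-propagated values", {
  dag <- benchmark_dag()
  sim <- simulate_dag(dag, 0, 10000, "g6", 0, seed = 76)
  # with g6 clamped to 0, g9 = intercept + 3 * 0 + noise and
  # g12 = intercept + 1 * g9
  expect_equal(mean(sim$expr["g9", ]), 1.5, tolerance = 0.02)
  expect_equal(mean(sim$expr["g12", ]), 0.5 + 1.5, tolerance = 0.02)
})

test_that("an edgeless graph yields mutually independent nodes", {
  dag <- weighted_dag(4, intercepts = 0, residual_sd = 1)
  sim <- simulate_dag(dag, 10000, 0, seed = 77)
  cors <- stats::cor(t(sim$expr))
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.05))
})

test_that("pair simulation honours the generating model", {
  # alpha = 0 decouples X from G: KO values share X's WT marginal
  theta0 <- downstream_params(2, 0.5, 1, 0.4, 0)
  d <- simulate_pair("M1", theta0, 1e4, 1e4, do_value = 5, seed = 78)
  expect_gt(stats::ks.test(d$wt_x, d$ko_x)$p.value, 0.01)

  # noiseless boundary: KO values are exactly mu_x + alpha * do_value
  theta_n <- list(mu_g = 1, sigma_g = 0.2, mu_x = 3, sigma_x = 0, alpha = 2)
  dn <- simulate_pair("M1", theta_n, 5, 6, do_value = 1.5, seed = 79)
  expect_true(all(dn$ko_x == 3 + 2 * 1.5))

  # the two published variance regimes are reproduced empirically
  for (sds in list(c(0.09, 0.15), c(0.3, 0.5))) {
    theta <- downstream_params(2, sds[1], 1, sds[2], 1)
    big <- simulate_pair("M1", theta, 5000, 5000, 0, seed = 80)
    mc_sd_g <- sds[1] / sqrt(2 * (5000 - 1))
    expect_lt(abs(sd(big$wt_g) - sds[1]), 3 * mc_sd_g)
    resid <- big$wt_x - 1 - big$wt_g
    expect_lt(abs(sd(resid) - sds[2]), 3 * sds[2] / sqrt(2 * (5000 - 1)))
  }

  # M0: KO values follow X's marginal, not the do-shifted law
  b <- bivariate_params(2, 3, 0.3, 0.6, 0.7)
  dm0 <- simulate_pair("M0", b, 1e4, 1e4, do_value = 0, seed = 81)
  expect_equal(mean(dm0$ko_x), 3, tolerance = 0.03)
  expect_equal(sd(dm0$ko_x), 0.6, tolerance = 0.03)
  expect_equal(cor(dm0$wt_g, dm0$wt_x), 0.7, tolerance = 0.03)
})

test_that("matrix-accumulated total effects equal explicit path enumeration", {
  # single-path chain: product of edge weights
  chain <- weighted_dag(c("g6", "a", "b"),
                        data.frame(from = c("g6", "a"), to = c("a", "b"),
                                   weight = c(0.5, 2.0)))
  expect_equal(total_effect(chain, "g6", "b"), 1.0)
  expect_equal(total_effect(chain, "b", "g6"), 0) # no path

  # every DAG topology on 4 nodes (upper-triangular edge subsets)
  set.seed(82)
  nodes <- paste0("v", 1:4)
  pairs <- t(combn(4, 2))
  for (mask in 0:(2^nrow(pairs) - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0)
    edges <- data.frame(
      from = nodes[pairs[sel, 1]], to = nodes[pairs[sel, 2]],
      weight = stats::runif(length(sel), -2, 2),
      stringsAsFactors = FALSE
    )
    dag <- weighted_dag(nodes, edges)
    for (s in nodes) for (t in setdiff(nodes, s)) {
      expect_equal(total_effect(dag, s, t), path_sum_effect(dag, s, t),
                   tolerance = 1e-12)
    }
  }

  # random 6-node DAGs
  for (i in 1:25) {
    dag <- random_dag(6)
    s <- sample(dag$nodes, 1); t <- sample(setdiff(dag$nodes, s), 1)
    expect_equal(total_effect(dag, s, t), path_sum_effect(dag, s, t),
                 tolerance = 1e-12)
  }
})

test_that("the packaged benchmark DAG has the documented total effects and classes", {
  dag <- benchmark_dag()
  eff <- sapply(paste0("g", c(1:5, 7:13)),
                function(v) total_effect(dag, "g6", v))
  expect_equal(unname(eff[c("g9", "g10", "g11", "g12", "g13")]),
               c(3.00, -1.30, -0.02, 3.00, -1.30))
  expect_true(all(eff[paste0("g", c(1:5, 7, 8))] == 0))

  tt <- truth_table(dag, "g6")
  expect_setequal(tt$gene_id[tt$class == "downstream"],
                  paste0("g", 9:13))
  expect_setequal(tt$gene_id[tt$class == "upstream"], paste0("g", 1:3))
  expect_setequal(tt$gene_id[tt$class == "correlated"],
                  paste0("g", c(4, 5, 7, 8)))
  expect_identical(tt$downstream, tt$true_effect != 0)

  expect_true(all(dag$residual_sd >= 0.09 & dag$residual_sd <= 0.5))
})

test_that("cyclic graphs and unknown nodes are rejected with informative errors", {
  edges <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                      weight = 1)
  expect_error(weighted_dag(c("a", "b", "c"), edges), "cycle.*a.*b.*c")
  expect_error(
    weighted_dag("a", data.frame(from = "a", to = "z", weight = 1)),
    "unknown nodes: z"
  )
  dag <- benchmark_dag()
  expect_error(total_effect(dag, "g6", "nope"), "unknown node")
  expect_error(simulate_dag(dag, 2, 2, "nope"), "unknown do_node")
  expect_error(truth_table(dag, "nope"), "unknown do_node")
})
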