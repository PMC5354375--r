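#' Weighted directed acyclic graph for Gaussian structural-equation models
#'
#' Defines a linear Gaussian structural-equation model: each node equals its
#' intercept plus the weighted sum of its parents plus centred Gaussian
#' noise with the node's residual standard deviation. Edge weights are
#' direct causal effects; total causal effects accumulate over directed
#' paths (see [total_effect()]).
#'
#' @param nodes Character vector of unique node ids, or an integer count
#'   (nodes are then named `g1 ... gn`).
#' @param edges Data frame with columns `from`, `to`, `weight`. May have
#'   zero rows (fully disconnected graph).
#' @param intercepts Numeric vector of per-node intercepts, either named by
#'   node or positional; a single value is recycled. Default 0.
#' @param residual_sd Numeric vector of per-node residual standard
#'   deviations (>= 0; zero is a noiseless boundary useful in simulation),
#'   named or positional; a single value is recycled. Default 1.
#' @return An object of class `weighted_dag` with the nodes stored in a
#'   topological order.
#' @seealso [simulate_dag()], [total_effect()], [benchmark_dag()]
#' @export
weighted_dag <- function(nodes, edges = data.frame(from = character(0),
                                                   to = character(0),
                                                   weight = numeric(0)),
                         intercepts = 0, residual_sd = 1) {
  if (is.numeric(nodes) && length(nodes) == 1L) {
    nodes <- paste0("g", seq_len(nodes))
  }
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node ids must be unique")
  n <- length(nodes)
  if (n == 0L) stop("at least one node is required")

  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "weight") %in% names(edges))) {
    stop("edges must have columns from, to, weight")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  unknown <- setdiff(c(edges$from, edges$to), nodes)
  if (length(unknown) > 0) {
    stop(sprintf("edges reference unknown nodes: %s",
                 paste(unique(unknown), collapse = ", ")))
  }
  if (!all(is.finite(edges$weight))) stop("edge weights must be finite")
  if (anyDuplicated(edges[c("from", "to")])) stop("duplicated edges")

  expand <- function(v, what) {
    if (length(v) == 1L) v <- rep(v, n)
    if (!is.null(names(v))) {
      if (!all(nodes %in% names(v))) {
        stop(sprintf("%s must be provided for every node", what))
      }
      v <- v[nodes]
    } else if (length(v) != n) {
      stop(sprintf("%s must have length 1 or %d", what, n))
    }
    v <- as.numeric(v)
    names(v) <- nodes
    v
  }
  intercepts <- expand(intercepts, "intercepts")
  residual_sd <- expand(residual_sd, "residual_sd")
  if (!all(is.finite(intercepts))) stop("intercepts must be finite")
  if (any(residual_sd < 0)) stop("residual_sd must be >= 0")

  g <- igraph::graph_from_data_frame(edges[c("from", "to")],
                                     directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    loops <- edges$from[edges$from == edges$to]
    cyc <- unique(c(cyc, loops))
    stop(sprintf("graph contains a cycle involving nodes: %s",
                 paste(cyc, collapse = ", ")))
  }
  topo <- names(igraph::topo_sort(g, mode = "out"))

  structure(
    list(nodes = nodes, edges = edges, intercepts = intercepts,
         residual_sd = residual_sd, topo_order = topo),
    class = "weighted_dag"
  )
}

#' @export
print.weighted_dag <- function(x, ...) {
  cat(sprintf("<weighted_dag> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# direct-effect matrix W with W[parent, child] = edge weight
direct_effect_matrix <- function(dag) {
  n <- length(dag$nodes)
  W <- matrix(0, n, n, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$edges) > 0) {
    W[cbind(dag$edges$from, dag$edges$to)] <- dag$edges$weight
  }
  W
}

#' Exact total causal effect between two nodes of a weighted DAG
#'
#' The total causal effect of `source` on `target` is the sum over all
#' directed paths of the product of edge weights along each path. It is
#' computed in closed form as the (source, target) entry of
#' `solve(I - W)` where `W` is the direct-effect matrix — the matrix
#' geometric series `I + W + W^2 + ...` accumulates all path products and
#' terminates because the graph is acyclic. Zero when no directed path
#' exists.
#'
#' @param dag A [weighted_dag()].
#' @param source,target Node ids.
#' @return The scalar total causal effect.
#' @export
total_effect <- function(dag, source, target) {
  stopifnot(inherits(dag, "weighted_dag"))
  missing <- setdiff(c(source, target), dag$nodes)
  if (length(missing) > 0) {
    stop(sprintf("unknown node(s): %s", paste(missing, collapse = ", ")))
  }
  W <- direct_effect_matrix(dag)
  Tm <- solve(diag(length(dag$nodes)) - W)
  eff <- Tm[source, target]
  if (source == target) eff <- eff - 1
  eff
}

#' Simulate Gaussian structural-equation data on a DAG with an optional
#' knock-out intervention
#'
#' Wild-type samples are drawn from the observational model: in topological
#' order, each node equals its intercept plus the weighted sum of its
#' parents plus Gaussian noise. Knock-out samples apply Pearl's do-operator
#' to `do_node`: its incoming edges are severed and the node is clamped to
#' `do_value` (by default 0, the conventional representation of a
#' knock-out), while all other nodes keep their structural equations.
#'
#' @param dag A [weighted_dag()].
#' @param n_wt,n_ko Number of wild-type / knock-out samples (>= 0).
#' @param do_node Node receiving the intervention; required when
#'   `n_ko > 0`.
#' @param do_value Clamped value of `do_node` in KO samples; default 0.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `expr` (genes x samples numeric matrix), `condition`
#'   (per-sample `"WT"`/`"KO"` labels, named by sample id), `do_node` and
#'   `do_value`.
#' @export
simulate_dag <- function(dag, n_wt, n_ko = 0, do_node = NULL, do_value = 0,
                         seed = NULL) {
  stopifnot(inherits(dag, "weighted_dag"))
  if (n_wt < 0 || n_ko < 0) stop("sample counts must be >= 0")
  if (n_ko > 0 && is.null(do_node)) stop("do_node is required when n_ko > 0")
  if (!is.null(do_node) && !do_node %in% dag$nodes) {
    stop(sprintf("unknown do_node: %s", do_node))
  }
  if (!is.null(seed)) set.seed(seed)

  W <- direct_effect_matrix(dag)
  draw <- function(n, clamp) {
    m <- matrix(0, length(dag$nodes), n,
                dimnames = list(dag$nodes, NULL))
    if (n == 0) return(m)
    for (node in dag$topo_order) {
      if (!is.null(clamp) && node == clamp) {
        m[node, ] <- do_value
        next
      }
      parents <- dag$edges$from[dag$edges$to == node]
      val <- dag$intercepts[[node]] +
        stats::rnorm(n, 0, dag$residual_sd[[node]])
      if (length(parents) > 0) {
        val <- val + drop(W[parents, node] %*% m[parents, , drop = FALSE])
      }
      m[node, ] <- val
    }
    m
  }

  wt <- draw(n_wt, clamp = NULL)
  ko <- draw(n_ko, clamp = do_node)
  expr <- cbind(wt, ko)
  ids <- c(if (n_wt > 0) paste0("WT_", seq_len(n_wt)),
           if (n_ko > 0) paste0("KO_", seq_len(n_ko)))
  colnames(expr) <- ids
  condition <- stats::setNames(
    c(rep("WT", n_wt), rep("KO", n_ko)), ids
  )
  list(expr = expr, condition = condition,
       do_node = do_node, do_value = do_value)
}

#' Simulate an independent (G, X) pair under the downstream or correlated
#' model
#'
#' Under `"M1"` (downstream) the WT pairs follow the structural equations
#' `G ~ N(mu_g, sigma_g^2)`, `X = mu_x + alpha G + N(0, sigma_x^2)`, and the
#' KO values of X respond to the clamped G:
#' `X ~ N(mu_x + alpha * do_value, sigma_x^2)`. Under `"M0"` (upstream or
#' merely correlated) the WT pairs are drawn from the bivariate Gaussian
#' with parameters `params`, and the KO values of X keep X's observational
#' marginal `N(m2, s2^2)` — the intervention on G does not reach X.
#'
#' Zero standard deviations are accepted here (noiseless boundary cases),
#' although the fitting functions require positive variances.
#'
#' @param model `"M1"` or `"M0"`.
#' @param params A [downstream_params()] for `"M1"`, a [bivariate_params()]
#'   for `"M0"` (plain lists with the same fields are accepted, allowing
#'   zero sds).
#' @param n_wt,n_ko Sample counts (>= 0).
#' @param do_value Clamped value of G in KO samples; default 0.
#' @param seed Optional integer seed.
#' @return An [intervention_data()] object.
#' @export
simulate_pair <- function(model = c("M1", "M0"), params, n_wt, n_ko,
                          do_value = 0, seed = NULL) {
  model <- match.arg(model)
  if (n_wt < 0 || n_ko < 0) stop("sample counts must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  if (model == "M1") {
    required <- c("mu_g", "sigma_g", "mu_x", "sigma_x", "alpha")
    if (!all(required %in% names(params))) {
      stop("M1 requires downstream parameters (mu_g, sigma_g, mu_x, sigma_x, alpha)")
    }
    if (params$sigma_g < 0 || params$sigma_x < 0) {
      stop("standard deviations must be >= 0")
    }
    wt_g <- stats::rnorm(n_wt, params$mu_g, params$sigma_g)
    wt_x <- params$mu_x + params$alpha * wt_g +
      stats::rnorm(n_wt, 0, params$sigma_x)
    ko_x <- stats::rnorm(n_ko, params$mu_x + params$alpha * do_value,
                         params$sigma_x)
  } else {
    required <- c("m1", "m2", "s1", "s2", "rho")
    if (!all(required %in% names(params))) {
      stop("M0 requires bivariate parameters (m1, m2, s1, s2, rho)")
    }
    if (params$s1 < 0 || params$s2 < 0) stop("standard deviations must be >= 0")
    if (abs(params$rho) > 1) stop("rho must lie in [-1, 1]")
    Sigma <- matrix(c(params$s1^2,
                      params$rho * params$s1 * params$s2,
                      params$rho * params$s1 * params$s2,
                      params$s2^2), 2, 2)
    wt <- MASS::mvrnorm(n_wt, mu = c(params$m1, params$m2), Sigma = Sigma)
    wt <- matrix(wt, ncol = 2)
    wt_g <- wt[, 1]
    wt_x <- wt[, 2]
    ko_x <- stats::rnorm(n_ko, params$m2, params$s2)
  }
  intervention_data(wt_g = wt_g, wt_x = wt_x, ko_x = ko_x,
                    do_value = do_value)
}

#' Packaged 13-node benchmark DAG
#'
#' A fixed 13-node weighted DAG used throughout the package's validation
#' study. Node `g6` is the knock-out target and the graph contains all
#' three relationship classes a knocked-out gene can have:
#'
#' * upstream ancestors of `g6`: `g1`, `g2`, `g3`;
#' * genes merely correlated with `g6` through shared ancestry:
#'   `g4`, `g5`, `g7`, `g8`;
#' * downstream descendants: `g9` (total effect 3.00), `g10` (-1.30),
#'   `g11` (-0.02, deliberately near-undetectable), and `g12` (3.00) /
#'   `g13` (-1.30) reached through two-edge paths.
#'
#' Residual standard deviations lie in the 0.09-0.5 range typical of
#' log-scale expression data.
#'
#' @return A [weighted_dag()].
#' @export
benchmark_dag <- function() {
  edges <- data.frame(
    from = c("g1", "g2", "g3", "g1", "g3", "g4", "g1",
             "g6", "g6", "g6", "g9", "g10"),
    to   = c("g2", "g6", "g6", "g4", "g5", "g7", "g8",
             "g9", "g10", "g11", "g12", "g13"),
    weight = c(0.9, 0.8, -0.7, 1.1, 0.6, 0.5, -1.2,
               3.0, -1.3, -0.02, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
  intercepts <- c(g1 = 1.0, g2 = 0.5, g3 = 1.2, g4 = 0.6, g5 = 0.8,
                  g6 = 0.8, g7 = 0.9, g8 = 2.0, g9 = 1.5, g10 = 1.0,
                  g11 = 0.7, g12 = 0.5, g13 = 1.1)
  residual_sd <- c(g1 = 0.20, g2 = 0.15, g3 = 0.20, g4 = 0.25, g5 = 0.20,
                   g6 = 0.10, g7 = 0.20, g8 = 0.30, g9 = 0.20, g10 = 0.15,
                   g11 = 0.20, g12 = 0.25, g13 = 0.20)
  weighted_dag(paste0("g", 1:13), edges, intercepts, residual_sd)
}

#' Ground-truth relationship table for a DAG and intervention node
#'
#' Classifies every non-intervened node relative to `do_node` and records
#' its exact total causal effect: `downstream` (directed path from
#' `do_node`), `upstream` (directed path to `do_node`), `correlated`
#' (neither, but sharing a common ancestor, hence dependent), or
#' `independent`. The binary truth used by the evaluation harness labels a
#' gene downstream iff its total effect is nonzero.
#'
#' @param dag A [weighted_dag()].
#' @param do_node The intervened node.
#' @return A data frame with columns `gene_id`, `class`, `true_effect`,
#'   `downstream` (logical).
#' @export
truth_table <- function(dag, do_node) {
  stopifnot(inherits(dag, "weighted_dag"))
  if (!do_node %in% dag$nodes) stop(sprintf("unknown do_node: %s", do_node))
  g <- igraph::graph_from_data_frame(dag$edges[c("from", "to")],
                                     directed = TRUE,
                                     vertices = data.frame(name = dag$nodes))
  desc <- names(igraph::subcomponent(g, do_node, mode = "out"))
  anc <- names(igraph::subcomponent(g, do_node, mode = "in"))
  # ancestors-or-self sets, for detecting shared ancestry (confounding)
  anc_of <- function(v) names(igraph::subcomponent(g, v, mode = "in"))
  do_anc <- anc_of(do_node)

  genes <- setdiff(dag$nodes, do_node)
  cls <- vapply(genes, function(v) {
    if (v %in% desc) return("downstream")
    if (v %in% anc) return("upstream")
    if (length(intersect(anc_of(v), do_anc)) > 0) return("correlated")
    "independent"
  }, character(1))
  eff <- vapply(genes, function(v) total_effect(dag, do_node, v), numeric(1))
  data.frame(gene_id = genes, class = unname(cls),
             true_effect = unname(eff), downstream = unname(eff != 0),
             stringsAsFactors = FALSE)
}
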