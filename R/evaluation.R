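#' Rank-based area under the ROC curve
#'
#' Mann-Whitney form of the AUC: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, with ties counted 1/2.
#' Scores must be oriented so that larger means "more positive" (negate a
#' log10 Bayes factor before calling, since evidence for a downstream gene
#' is negative).
#'
#' @param scores Numeric ranking statistic, one per case.
#' @param labels Logical (or 0/1) truth, one per case; both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length")
  }
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must not contain NA")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both a positive and a negative label are required")
  }
  r <- rank(scores) # average ranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Recall, precision and F-score of a binary classification
#'
#' F is the harmonic mean `2RP / (R + P)`. Degenerate denominators (no true
#' positives reachable, or no predicted positives) yield 0 for the affected
#' statistic and set the `degenerate` flag rather than erroring.
#'
#' @param predicted Logical (or 0/1) predictions.
#' @param truth Logical (or 0/1) ground truth, same length.
#' @return A list with `recall`, `precision`, `f` and `degenerate`.
#' @export
fscore <- function(predicted, truth) {
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have the same length")
  }
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  degenerate <- (tp + fn) == 0 || (tp + fp) == 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  list(recall = recall, precision = precision, f = f,
       degenerate = degenerate)
}

# Newton inversion of the trigamma function, used to moment-match the
# prior degrees of freedom from the spread of the log sample variances.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    step <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + step
    if (abs(step) < 1e-10 * y) break
  }
  y
}

#' Moderated two-sample t-test with empirical-Bayes variance shrinkage
#'
#' A self-contained differential-analysis baseline: per-gene pooled sample
#' variances are shrunk toward an ensemble prior variance before forming
#' the two-sample t-statistic. Under the standard hierarchical model the
#' per-gene variances follow a scaled F distribution around the prior
#' variance `s0^2` with prior degrees of freedom `d0`; both are estimated
#' by moment-matching the mean and spread of the log sample variances
#' (using digamma/trigamma identities for log chi-square moments). The
#' moderated statistic uses the posterior variance
#' `(d0 s0^2 + d s^2) / (d0 + d)` and is referred to a t distribution with
#' `d0 + d` degrees of freedom.
#'
#' With `prior_df = 0` the ordinary pooled two-sample t-test is recovered
#' exactly; with `prior_df = Inf` all genes share the ensemble variance.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param conditions Per-sample `"WT"`/`"KO"` labels aligned with columns.
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom (e.g. 0 or Inf).
#' @return A data frame with one row per gene: `gene_id`, `log_fc`
#'   (KO mean - WT mean), `t`, `df`, `p_value`, `p_adj`
#'   (Benjamini-Hochberg), `zero_variance` flag. The estimated `prior_df`
#'   and `prior_var` are attached as attributes.
#' @export
moderated_t <- function(expr, conditions, prior_df = NULL) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop("at least 2 genes are required for shrinkage")
  conditions <- as.character(conditions)
  if (length(conditions) != ncol(expr)) {
    stop("conditions must have one label per sample")
  }
  wt_idx <- which(conditions == "WT")
  ko_idx <- which(conditions == "KO")
  n1 <- length(wt_idx)
  n2 <- length(ko_idx)
  if (n1 < 2L || n2 < 2L) stop("at least 2 samples per condition are required")

  m_wt <- rowMeans(expr[, wt_idx, drop = FALSE])
  m_ko <- rowMeans(expr[, ko_idx, drop = FALSE])
  ss_wt <- rowSums((expr[, wt_idx, drop = FALSE] - m_wt)^2)
  ss_ko <- rowSums((expr[, ko_idx, drop = FALSE] - m_ko)^2)
  d <- n1 + n2 - 2
  s2 <- (ss_wt + ss_ko) / d
  zero_var <- s2 == 0

  # moment-match the log-variance distribution:
  # z = log(s2) has mean log(s0^2) + digamma(d/2) - log(d/2)
  #                    - digamma(d0/2) + log(d0/2)
  # and variance trigamma(d/2) + trigamma(d0/2)
  z <- log(s2[!zero_var])
  if (length(z) < 2L) stop("too few genes with positive variance")
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) * (length(e) - 1) / length(e) - trigamma(d / 2)
  if (is.null(prior_df)) {
    d0 <- if (evar > 0) 2 * trigamma_inverse(evar) else Inf
  } else {
    d0 <- prior_df
  }
  s0_2 <- if (is.finite(d0) && d0 > 0) {
    exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    exp(mean(e))
  }

  s2_post <- if (is.finite(d0)) {
    if (d0 == 0) s2 else (d0 * s0_2 + d * s2) / (d0 + d)
  } else {
    rep(s0_2, length(s2))
  }
  if (d0 == 0 && any(zero_var)) s2_post[zero_var] <- s0_2

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  log_fc <- m_ko - m_wt
  tstat <- log_fc / se
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  out <- data.frame(
    gene_id = if (is.null(rownames(expr))) as.character(seq_len(nrow(expr)))
              else rownames(expr),
    log_fc = unname(log_fc),
    t = unname(tstat),
    df = df_total,
    p_value = unname(p),
    p_adj = unname(stats::p.adjust(p, method = "BH")),
    zero_variance = unname(zero_var),
    stringsAsFactors = FALSE
  )
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s0_2
  out
}

#' Benchmark the causal Bayes-factor screen against the moderated t-test
#'
#' Reproduces the package's validation comparison: for each per-arm sample
#' size in `settings` and each replicate, data are simulated from `dag`
#' with a knock-out of `do_node`, both methods are run, and their ability
#' to retrieve the truly downstream genes (nonzero total causal effect) is
#' summarised by the rank AUC; the thresholded Bayes-factor classification
#' is additionally summarised by recall, precision and F-score.
#'
#' @param dag A [weighted_dag()].
#' @param do_node Intervened node.
#' @param settings Integer vector of per-arm sample sizes, e.g.
#'   `c(5, 10, 25)` for 5 WT / 5 KO etc.
#' @param n_replicates Simulations per setting.
#' @param do_value Clamped value of the knock-out; default 0.
#' @param threshold log10 Bayes-factor classification threshold; default
#'   -0.5.
#' @param seed Root seed; per-replicate child seeds are derived from it so
#'   results do not depend on evaluation order.
#' @return A tidy data frame with columns `setting`, `replicate`, `method`
#'   (`"bayes_factor"` or `"moderated_t"`), `metric` (`"auc"`, `"recall"`,
#'   `"precision"`, `"fscore"`) and `value`.
#' @export
run_benchmark <- function(dag, do_node, settings = c(5, 10, 25),
                          n_replicates = 100, do_value = 0,
                          threshold = -0.5, seed = 1) {
  stopifnot(inherits(dag, "weighted_dag"))
  truth <- truth_table(dag, do_node)
  if (!any(truth$downstream) || all(truth$downstream)) {
    stop("the DAG must contain both downstream and non-downstream genes")
  }
  set.seed(seed)
  child_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, length(settings) * n_replicates),
    nrow = length(settings)
  )

  rows <- list()
  for (si in seq_along(settings)) {
    n <- settings[si]
    for (rep_i in seq_len(n_replicates)) {
      sim <- simulate_dag(dag, n_wt = n, n_ko = n, do_node = do_node,
                          do_value = do_value,
                          seed = child_seeds[si, rep_i])
      screen <- screen_genes(sim$expr, do_node, sim$condition,
                             do_value = do_value, threshold = threshold)
      screen <- screen[match(truth$gene_id, screen$gene_id), ]
      bf_score <- -screen$log10_bf
      bf_score[is.na(bf_score)] <- 0 # failed fits carry no evidence

      mt <- moderated_t(sim$expr[truth$gene_id, , drop = FALSE],
                        sim$condition)
      t_score <- -log(pmax(mt$p_value, .Machine$double.xmin))

      fs <- fscore(!is.na(screen$log10_bf) & screen$log10_bf < threshold,
                   truth$downstream)
      rows[[length(rows) + 1L]] <- data.frame(
        setting = n, replicate = rep_i,
        method = c("bayes_factor", "moderated_t",
                   "bayes_factor", "bayes_factor", "bayes_factor"),
        metric = c("auc", "auc", "recall", "precision", "fscore"),
        value = c(rank_auc(bf_score, truth$downstream),
                  rank_auc(t_score, truth$downstream),
                  fs$recall, fs$precision, fs$f),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
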