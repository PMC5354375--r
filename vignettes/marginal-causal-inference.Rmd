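---
title: "Marginal causal inference from single-gene knock-out expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal causal inference from single-gene knock-out expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(margcausal)
```

## The problem

Transcriptomic experiments sometimes combine replicated observational
(wild-type, WT) expression profiles with interventional profiles in which a
single gene G has been knocked out. Full causal-network inference from such
data is rarely feasible: the number of genes vastly exceeds the number of
replicates, and with an intervention on only one node most of the graph
remains in a large equivalence class. `margcausal` instead answers a
*marginal* question, gene by gene: **is candidate gene X downstream of the
knocked-out gene G** — so that the intervention propagates to X — or is the
association between them explained by X being upstream of G or merely
correlated with it? Because the question is marginal, the procedure scales
to many thousands of genes and also yields an estimate of the total causal
effect of G on each X.

## The model

All relationships are modelled as linear Gaussian structural equations on an
(unknown) acyclic graph. For a single pair (G, X), three observational
situations can arise: X is a child of G (downstream), G is a child of X
(upstream), or the two are dependent without either being an ancestor of the
other (correlated). All three induce a bivariate Gaussian joint law for
(G, X), and on observational data alone they are Markov equivalent — any of
them can be reparameterized as the *downstream* form

$$G \sim N(\mu_G, \sigma_G^2), \qquad X = \mu_X + \alpha G + \varepsilon_X,
  \quad \varepsilon_X \sim N(0, \sigma_X^2),$$

with $\alpha$ the total causal effect of G on X. The bivariate form
$(m_1, m_2, s_1, s_2, \rho)$ and the downstream form
$(\mu_G, \sigma_G, \mu_X, \sigma_X, \alpha)$ are exact bijections of one
another (`as_downstream()`, `as_bivariate()`; the symmetric upstream
reparameterization is available as `as_upstream()` for completeness).

The intervention breaks the equivalence. A knock-out is modelled with
Pearl's do-operator: do(G = g) deletes every edge into G and clamps G to
$g$ (taken to be 0 by default, the conventional encoding of an expression
knock-out). Under do(G = g):

* if X is downstream (model **M1**), X responds:
  $X \mid \mathrm{do}(G = g) \sim N(\mu_X + \alpha g, \sigma_X^2)$;
* if X is upstream or merely correlated (pooled into model **M0**), X is
  untouched and keeps its observational marginal
  $X \sim N(\mu_X + \alpha\mu_G,\ \alpha^2\sigma_G^2 + \sigma_X^2)$.

The upstream and correlated cases are pooled into M0 deliberately: under an
intervention on G both reduce to X's marginal, so they remain mutually
indistinguishable, while either is distinguishable from the downstream
model.

Writing WT for the observational samples and KO for the interventional
ones, both models share the observational term

$$l_{WT}(\theta) = \sum_{k \in WT} \log N(x_k;\ \mu_X + \alpha g_k,\ \sigma_X^2)
  + \log N(g_k;\ \mu_G,\ \sigma_G^2)$$

and differ in the KO term, giving $l_{M1} = l_{WT} + l_{KO1}$ and
$l_{M0} = l_{WT} + l_{KO2}$ with the two KO densities above
(`loglik_m1()`, `loglik_m0()` and their components). Both models use the
*same* five parameters $\theta$.

## Model selection and effect estimation

Each likelihood is maximized and the models are compared through a Bayes
factor on the log10 scale:

$$\log_{10} B = \frac{\max_\theta l_{M0} - \max_\theta l_{M1}}{\ln 10}
  + \log_{10}(\text{prior odds}).$$

Negative values favour the downstream model; the more negative, the
stronger the downstream evidence, so sorting genes by $\log_{10} B$ ranks
them by the strength of the downstream causal relationship. Because exact
model evidences $P(\text{data} \mid M_i)$ require a prior on $\theta$ that
the empirical-Bayes construction does not supply, the package uses the
maximized-likelihood ratio directly. This is a deliberate design
choice: the two models share the identical 5-dimensional parameter space,
so any complexity penalty of the AIC/BIC family cancels exactly and the
penalized ratio *equals* the maximized-likelihood ratio. Prior model odds
default to 1 and are exposed as an argument.

The total causal effect is estimated as $\hat\alpha$ from the M1 fit.

Key numerical facts:

* **M1 has a closed-form global maximizer** (`fit_m1()`): the likelihood
  factorizes into a Gaussian regression of X on G over the *pooled* WT and
  KO samples (KO samples enter with G fixed at the do-value) and a Gaussian
  marginal for G over the WT samples, so the MLE is the least-squares
  intercept/slope with 1/n residual variances. The test suite verifies the
  closed form against a generic numeric optimizer.
* **M0 is maximized numerically** (`fit_m0()`): BFGS on
  $(\mu_G, \log\sigma_G, \mu_X, \log\sigma_X, \alpha)$ — the log scale
  enforces positive variances — from two starting points (the M1 solution
  and a moment estimate of the implied bivariate law), keeping the better
  optimum; the returned fit is guaranteed to score at least as well as
  every start. Relative tolerance 1e-12, at most 500 iterations, no
  randomness: fitting is deterministic given the data.
* **No KO samples** makes the two objectives identical; `bayes_factor()`
  recognizes this case and returns exactly $\log_{10}(\text{prior odds})$
  rather than relying on two optimizers agreeing to rounding error.
* Degenerate inputs (constant genes, collinear WT pairs) are reported as
  errors by the fitting functions; `screen_genes()` converts them into
  flagged result rows with `NA` statistics so output rows always align with
  input genes.

Classification uses a hard threshold on the log10 Bayes factor, default
**-0.5**, exposed everywhere as an argument. The threshold trades recall
for precision; the benchmark harness reports recall/precision/F-score so
users can recalibrate it for their own noise regime.

## The simulator and what it emulates

`simulate_dag()` draws from a linear Gaussian structural-equation model on
a `weighted_dag()`: in topological order, each node is its intercept plus
the weighted sum of its parents plus centred Gaussian noise. KO samples
clamp the intervened node and sever its incoming edges — exactly the
do-semantics assumed by the likelihoods. `simulate_pair()` draws single
(G, X) pairs under M1 or M0. `total_effect()` gives the exact total causal
effect as the source–target entry of $(I - W)^{-1}$, where $W$ is the
direct-effect matrix; this matrix geometric series equals the sum over all
directed paths of the product of edge weights, and the tests verify it
against explicit path enumeration.

`benchmark_dag()` packages the fixed 13-node graph used in the validation
study: knock-out node `g6`; upstream ancestors `g1`–`g3`; genes correlated
with `g6` through shared ancestry (`g4`, `g5`, `g7`, `g8`); and five
downstream genes with total effects 3.00 (`g9`, directly), -1.30 (`g10`),
-0.02 (`g11`, deliberately near-undetectable), and 3.00 / -1.30 again
(`g12`, `g13`) through two-edge paths — so the three relationship classes
and both path structures occur. Residual standard deviations (0.09–0.5)
span the low/high-variance regimes typical of log-scale expression data;
intercepts are arbitrary constants of order 1 on the same scale. Pair
simulations use $\mu_G = 2$, $\mu_X = 1$, $\alpha = 1$ by default in the
validation tests: only the variances materially drive the separation of
the Bayes factors (through the signal-to-noise ratio
$\alpha(\mu_G - g)/\sigma$), so these means are fixed once at
representative log-expression values.

The simulator emulates the *assumptions of the model*: linearity,
Gaussian noise, acyclicity, a perfectly clamped knock-out and i.i.d.
replicates. It deliberately does not emulate features of real
transcriptomic data such as array/batch effects, normalization artifacts,
mean–variance dependence, latent confounders, feedback loops or an
imperfect ("leaky") knock-out. Passing validation therefore demonstrates
correctness of the implementation and behaviour of the method *under its
own assumptions*, not robustness to their violation.

Reproducibility discipline: every simulation accepts a seed, and the
multi-replicate harnesses derive per-replicate child seeds from one root
seed, so results are independent of evaluation order and bit-identical
across runs.

## The differential-analysis baseline

As a comparison point, `moderated_t()` implements a self-contained
moderated two-sample t-test with empirical-Bayes variance shrinkage: the
per-gene pooled variances are modelled as scaled-F fluctuations around an
ensemble prior variance, the prior degrees of freedom and scale are
estimated by moment-matching the mean and spread of the log sample
variances (digamma/trigamma identities), and the moderated statistic is
referred to a t distribution with augmented degrees of freedom. Setting
the prior degrees of freedom to 0 recovers the ordinary pooled t-test
exactly; the tests check both this identity and the null calibration
(uniform p-values) of the estimated version, and cross-check the statistic
against an established implementation of the same shrinkage construction.

`run_benchmark()` ties everything together: simulate from a DAG, screen
with the Bayes factor, test with the moderated t, and score both by rank
AUC for retrieving the truly downstream genes (truth: nonzero exact total
effect — which labels the -0.02 gene positive, and hence hard, on the
benchmark DAG) plus recall/precision/F-score for the thresholded
classification. Ranking by the moderated-t p-value is equivalent under AUC
to any monotone transform of it, so no multiple-testing adjustment enters
the comparison; adjusted p-values are nevertheless reported by
`moderated_t()` (Benjamini–Hochberg) for direct use.

## Validation study sizes

The packaged validation (test suite and `scripts/acceptance.R`) uses 100
simulated datasets per configuration: total-effect recovery at 6, 12, 24
and 48 replicates per arm; Bayes-factor separation for 100 independent
pairs at 24 + 24 under both variance regimes; downstream classification on
the benchmark DAG at 24 + 24; and the method comparison at 5 + 5 and
25 + 25 replicates. These sizes mirror the experimental designs the method
targets (a few dozen replicates per arm at most) while keeping each
validation configuration comfortably reproducible on a laptop.

## Known limitations

* Linear Gaussian structural equations and acyclicity are assumed, not
  tested; strongly non-linear regulation or feedback will violate both.
* The knock-out is treated as a perfect intervention clamping G to a known
  value. Functional knock-outs that merely attenuate activity weaken the
  contrast between the models.
* The marginal question cannot distinguish upstream from correlated
  relationships (they are pooled into M0 by construction), and gives no
  adjusted/conditional effects.
* Very small total effects are statistically invisible at realistic
  replicate counts — on the benchmark DAG the -0.02 gene is typically not
  detected, by design.
* The Bayes factor uses maximized likelihoods with equal prior odds; it is
  an evidence *ranking* device, and its hard threshold (-0.5 by default)
  is a calibration choice, not a frequentist error guarantee.
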