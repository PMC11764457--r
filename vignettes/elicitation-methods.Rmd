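---
title: "From expert quartile judgments to informative network priors"
author: "elicitbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expert quartile judgments to informative network priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elicitbn)
```

## The problem

Survival prediction for pancreatic cancer rests on variables measured
at diagnosis — serum CA 19-9, tumor size, age, resectability status —
most of which lack an agreed threshold or reference category. A
Bayesian network can use such variables jointly, but every root node
needs a prior, and when data are scarce the prior must come from
somewhere other than the data. Structured expert elicitation supplies
it: a panel of specialists states, for each quantity of interest, a
plausible range together with the lower quartile, median and upper
quartile. This package turns such quartile judgments into informative
priors for a hybrid (mixed continuous/categorical) Bayesian network,
and provides the network machinery — forward sampling, evidence
conditioning, prior-regime comparison — to use them.

## The elicitation-to-prior procedure

**Standardization.** Each expert's five summaries are mapped to
quantile points. The quartiles carry probabilities 0.25 / 0.5 / 0.75;
the plausible limits are treated as near-certain bounds and carry a
configurable tail probability (default 0.01, i.e. the limits become the
1st and 99th percentiles). The published protocol standardizes
intervals to damp overconfidence but does not state the tail mass; 0.01
follows common quartile-method practice and is exposed as
`tail_probability`. By default the limit points enter the least-squares
fit alongside the quartiles (`fit_quartiles_only = FALSE` flips this),
so every family is scored on the same five points.

**Complete cases.** Experts who left any of the five summaries blank,
or answered with all-identical null values, are dropped *per node*
(`complete_case_filter()`). The retained count $n$ matters later: the
pooled continuous prior uses $df = n - 1$.

**Per-expert fitting.** Eight candidate families are fitted to each
assessment by least squares on quantiles,

$$\hat\theta_f = \arg\min_\theta \sum_j \big(q_j - Q_f(p_j;\theta)\big)^2,$$

over normal, location-scale Student-T, shifted gamma, mirror gamma,
(shifted) lognormal, log-T, mirror log-T and shifted-scaled beta. The
mirror families reflect a positive-support shape about a finite upper
bound, producing the left-skewed shapes typical of age or tumor-size
judgments; when the node's catalog support is unbounded above, the
expert's own upper plausible limit is used as the reflection bound
(`mirror_bound = "elicited"`, the default — without it no mirror family
could ever win on a `[0, Inf)` node, contradicting how such elicited
panels behave in practice). Per-expert T-type fits fix the degrees of
freedom at 3, a conventional heavy-tail elicitation default exposed as
`df_fixed`; the published $df = n - 1$ rule applies to the *pooled*
prior, not per-expert fits. The optimizer is Nelder-Mead from
moment-matched starting values with five seeded jittered restarts and a
final polish (relative tolerance $10^{-12}$); noiseless five-point
assessments are recovered to sse $< 10^{-8}$ and parameters within 1%
(a tested property). The family with the lowest sse wins; near-ties
(within $10^{-10}$ relative) go to the earlier family in the fixed
listing order normal, T, shifted gamma, mirror gamma, lognormal, log-T,
mirror log-T, shifted-scaled beta, since the protocol reports a single
best fit and states no tie rule.

**Pooling.** Experts are equally weighted regardless of seniority — the
published protocol's rule, hard-defaulted here (unequal weights require
an explicit argument). The linear pool is the mixture
$f(x) = \sum_i w_i f_i(x)$; its moments are closed-form,

$$\mu = \sum_i w_i m_i, \qquad
  \sigma^2 = \sum_i w_i (v_i + m_i^2) - \mu^2,$$

and its quantile function is the numeric inverse of the mixture CDF
(bisection bracketed on the union of component $10^{-6}$ quantiles,
tolerance $10^{-8}$). Components without finite moments — the log-T
types at any df, T-types at $df \le 2$ — would otherwise crash the
pipeline; `pool_moments()` substitutes conditional moments on the
central 0.001–0.999 quantile range and flags the result `truncated`.
The family census (`concordance()`) counts each expert's best-fit
family and reports the modal one as `"Family (k/n)"`.

**Priors.** Proportion nodes get a beta prior. The default route is
moment matching: with $c = \mu(1-\mu)/\sigma^2 - 1$,
$\alpha = \mu c$ and $\beta = (1-\mu)c$ — the standard transform, whose
correctness here is corroborated by its numerical agreement with the
published shape parameters (e.g. pooled mean 0.56, SD 0.13 gives
$\alpha = 7.60$ against a printed 7.62). Moment pairs with
$\sigma^2 \ge \mu(1-\mu)$ admit no beta; they are flagged with the
violated bound and never silently repaired (a genuine pooled
distribution on $[0,1]$ cannot be infeasible, so a flag almost always
means a transcription error in the inputs). The alternative
`beta_quantile` route least-squares a beta quantile function to the
pooled quantiles at $\{0.01, 0.25, 0.5, 0.75, 0.99\}$, for pools whose
shape a single moment-matched beta represents poorly. Continuous nodes
get a location-scale Student-T on the pooled moments with
$df = n - 1$ (`pooled_moment_t`), or `refit_best_family`, which re-runs
the best-fit search on the pooled quantile grid — the route by which a
mirror-log-T pooled prior arises for left-skewed nodes. Lognormal and
log-T fits are shifted by the node's finite lower support bound and
anchored at zero otherwise.

## The hybrid network

Nodes are typed (continuous/categorical); roots carry priors, children
carry conditional models (`cpt`/`tabulated` tables, `linear`,
`logistic`, `multinomial`), and edges are derived from each model's
response/explanatory names, so specifying the node models specifies the
DAG. Inference is self-contained sampling — ancestral forward sampling
plus likelihood weighting for evidence — rather than an external
Gibbs/MCMC engine: at twelve-node scale this is dependency-free,
exactly reproducible under a seed, and (a tested property) agrees with
brute-force enumeration on small discrete networks to Monte-Carlo
error.

Two semantics are offered for beta-prior categorical roots.
`"predictive"` (default) draws a proportion from the beta prior per
replicate and then the category — prior-predictive sampling, which
propagates elicitation uncertainty; `"fixed"` plugs in the beta mean.
The published description does not say which its tooling used, so both
are kept one flag apart. Continuous roots are sampled by inverse-CDF
restricted to the node support (a Student-T prior for a non-negative
marker is effectively truncated at 0; the truncation constant is
likewise applied when weighting evidence). Note that normal or T fits
to proportion nodes are *not* truncated to $[0,1]$ during fitting —
they compete on quantile error like every family — which is why a
pooled proportion can, with printed rather than computed moments, fail
the beta feasibility bound.

`compare_prior_regimes()` runs the same query under two structurally
identical networks (informative vs `noninformative_network()`, which
flattens betas to Beta(1, 1) and widens continuous priors about their
median) and reports posterior summaries plus total-variation distances
on categorical nodes — the scaffold for informative-vs-flat sensitivity
analysis. Without evidence the divergence is the prior divergence; as
evidence accumulates on a node the regimes reconcile.

### The shipped replica configuration

`inst/extdata/paper_replica.yaml` instantiates the twelve
diagnosis-time variables (CA 19-9 UI/mL, age in years, tumor size in
mm, and nine dichotomous clinical factors whose elicited proportion
refers to the first-listed category) with their published pooled
priors. Two deliberate representation choices:

* **It ships edgeless.** The published DAG figure's edge list is not
  machine-readable, and inventing conditional-model parameters would
  put numbers into the replica that no elicitation produced. All twelve
  nodes are therefore roots carrying their elicited marginal priors;
  users connect them by supplying conditional models.
* **Continuous priors are location-scale T stand-ins.** The published
  best-fit labels for age and tumor size are mirror-log-T, but only the
  pooled mean/SD (with $df = n-1$) were published, not the underlying
  mirror-log-T parameters; the replica therefore encodes all three
  continuous priors as Student-T of the pooled moments, truncated to
  support when sampled, and says so in the file header.

## The synthetic panel generator

`panel_config()`/`simulate_panel()` emulate the study conditions: a
panel (the preset `paper_like_config()` uses 9 experts, matching the
study's respondent count) judging 12 nodes — 10 proportions and 3
positive continuous quantities — with designated incomplete responses
(2 for age, 1 for tumor size, 1 for CA 19-9, reproducing the published
complete-case denominators 7, 8 and 8). Each expert reports the true
distribution's (0.01, 0.25, 0.5, 0.75, 0.99) quantiles perturbed by
multiplicative Gaussian noise (default relative SD 0.05 in the preset —
a mild disagreement level chosen once as realistic for specialists
judging quantities they see daily), truncated at support and re-sorted.
Multiplicative noise is used because node scales span four orders of
magnitude (proportions vs CA 19-9 in UI/mL). All randomness flows from
the single config seed.

The preset's true distributions are chosen so pooled moments
*approximate* the published pooled summaries (betas use the published
shape pairs; CA 19-9 a moment-matched lognormal; age a mirror-gamma
about 100 years; tumor size a shifted gamma). What passing tests on
such panels show: the fitting/pooling/prior chain recovers known
ground truth under panel-like noise and missingness. What they do not
show: anything about real expert behaviour — anchoring, herding,
systematic overconfidence beyond the noise knob, or the group-consensus
revision step of a live workshop, none of which are modelled.

## Numerical choices and degenerate inputs

* Quantile-fit objective guarded against invalid parameter proposals
  (penalty $10^{10}$); transformed (log-scale) parameters capped at
  $e^{\pm 40}$.
* Pooled-quantile inversion tolerance $10^{-8}$; truncated-moment
  quadrature relative tolerance $10^{-8}$ on the 0.001–0.999 range.
* Tail evidence: likelihood weighting reports the effective sample
  size $(\sum w)^2 / \sum w^2$; all-zero weights (structurally
  impossible evidence) raise a degenerate-evidence error rather than
  returning an empty posterior.
* Judgments with all-identical values are incomplete (a null
  response), not monotone-valid data; monotonicity violations among
  complete rows are hard errors naming the expert and node.
* Fewer than two complete judgments for a node is an insufficient
  panel: pooling requires a genuine mixture.

## Problem sizes used by the test suite

Distributional oracles use $10^6$ Monte-Carlo draws; likelihood
weighting is checked at $10^5$ draws against exact enumeration on
binary networks; recovery experiments use panels of 6–9 experts with
8–30 seeded replicates per noise level; the replica network is sampled
at $n = 1000$. These sizes make every check pass or fail within
Monte-Carlo bands stated in the tests themselves.

## Known limitations

* No survival-outcome node is parameterized — no outcome model was
  published — so the network models the diagnostic-time joint
  distribution, not survival itself.
* Least squares on quantiles is the only fitting criterion (no ML or
  Bayesian fitting of judgments), per the elicitation protocol.
* Only the eight listed families are supported; no semi-parametric
  priors.
* Conditional probabilities for child nodes must be user-supplied; the
  package deliberately provides no mapping from marginal elicitation
  instruments to conditional tables.

## A worked example

```{r example, eval = FALSE}
library(elicitbn)

cfg <- paper_like_config(seed = 11)
panel <- simulate_panel(cfg)
rec <- recovery_experiment(cfg)
rec$per_node[, c("node_id", "pooled_mean", "pooled_sd", "prior",
                 "concordance")]

bn <- read_network_config(system.file("extdata", "paper_replica.yaml",
                                      package = "elicitbn"))
post <- condition_network(bn, list(ca19_9 = 500, age = 75), n = 1e4,
                          seed = 1)
posterior_summary(post)$resectability
```
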