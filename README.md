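# elicitbn

Expert-elicited informative priors and hybrid Bayesian networks for
clinical prognosis modelling.

Many prognostic variables available at a pancreatic-cancer diagnosis —
serum CA 19-9 (UI/mL), tumor size (mm), age, resectability status,
tumor location — lack agreed thresholds, so a survival network built
on them cannot rely on flat priors and sparse data alone. `elicitbn`
implements the full pipeline from structured expert elicitation to a
sampleable hybrid Bayesian network:

1. **Quartile judgments.** Each expert supplies, per quantity of
   interest, a plausible range plus the lower quartile, median and
   upper quartile. Judgments are validated (monotonicity, support),
   incomplete responses are flagged, and a per-node complete-case
   filter determines the usable panel size *n*.
2. **Least-squares quantile fitting.** Every complete judgment is
   fitted over eight candidate families — normal, Student-T, shifted
   gamma, mirror gamma, lognormal, log-T, mirror log-T, shifted-scaled
   beta — by minimising
   `sum_j (q_j − Q(p_j; θ))²`, and the family with the lowest sum of
   squared quantile deviations wins.
3. **Linear opinion pooling.** Per-expert fits are combined with equal
   weights into the mixture `f(x) = Σ w_i f_i(x)`, with closed-form
   pooled moments `μ = Σ w_i m_i`,
   `σ² = Σ w_i (v_i + m_i²) − μ²`, numeric pooled quantiles, and a
   family-concordance census (`"T (6/8)"`-style).
4. **Informative priors.** Proportion nodes get a beta prior by moment
   matching — `c = μ(1−μ)/σ² − 1`, `α = μc`, `β = (1−μ)c` — or by
   quantile interpolation; continuous nodes get a location-scale
   Student-T on the pooled moments with `df = n − 1`, or a refitted
   best family on the pooled quantile grid. Beta-infeasible moment
   pairs (`σ² ≥ μ(1−μ)`) are flagged, never repaired.
5. **Hybrid Bayesian network.** Typed nodes (continuous/categorical),
   conditional model classes (`cpt`, `tabulated`, `linear`,
   `logistic`, `multinomial`), edges derived from model
   response/explanatory names, ancestral forward sampling, evidence
   conditioning by likelihood weighting, DOT export, and
   informative-vs-flat prior-regime comparison.
6. **Synthetic panels.** A seeded generator with known ground truth
   (including a 9-expert, 12-node preset with realistic incomplete
   responses) makes every stage testable end to end.

## Worked example

Simulate a 9-expert panel over the twelve clinical variables, run
fits, pooling and priors, and inspect the per-node summary:

```r
library(elicitbn)

rec <- recovery_experiment(paper_like_config(seed = 11))
rec$per_node[, c("node_id", "pooled_mean", "pooled_sd", "n_experts",
                 "concordance", "prior")]
#>            node_id pooled_mean pooled_sd n_experts        concordance
#>             ca19_9    127.7736 202.37022         8    LogNormal (8/8)
#>                age     69.4509  16.64450         7  MirrorGamma (5/7)
#>         tumor_size     24.0376  11.45715         8 ShiftedGamma (8/8)
#>             gender      0.5714   0.13287         9       Normal (7/9)
#>  ...
#>                       prior
#>  T (127.77, 202.37, df = 7)
#>    T (69.45, 16.64, df = 6)
#>    T (24.04, 11.46, df = 7)
#>           Beta (7.35, 5.52)
#>  ...
```

Reading the first row: one expert's CA 19-9 response was incomplete,
so 8 of 9 experts enter the pool (`df = 8 − 1 = 7` in the prior
string); all 8 best-fits landed on the lognormal family
(`LogNormal (8/8)`); and the pooled mean/SD of roughly 128/202 UI/mL
recover the generating distribution's 130/208 to sampling error. The
`gender` row pools nine complete judgments to mean 0.571 (the expected
proportion of male patients) and a `Beta (7.35, 5.52)` prior.

Moment matching on its own is one call:

```r
format_prior(beta_from_moments(0.56, 0.13))
#> [1] "Beta (7.60, 5.98)"
format_prior(t_prior_from_pool(130.29, 207.84, n_experts = 8))
#> [1] "T (130.29, 207.84, df = 7)"
```

The shipped twelve-node configuration builds and samples directly:

```r
bn <- read_network_config(system.file("extdata", "paper_replica.yaml",
                                      package = "elicitbn"))
smp <- forward_sample(bn, 10000, seed = 1)
mean(smp$gender == "male")
#> [1] 0.5659      # ~ 7.62 / (7.62 + 5.76), the beta-prior mean
```

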