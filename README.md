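# dietbhm

Bayesian hierarchical negative binomial regression for diet–gut-microbiome
association studies.

Cohorts that collect food-frequency questionnaires (FFQ) alongside 16S
rRNA microbiome profiles ask, per food item and per OTU, whether microbial
abundance changes with consumption. OTU count tables fight back: library
sizes vary by orders of magnitude, counts are over-dispersed and
zero-rich, and per-OTU dispersion estimates are unstable. `dietbhm` fits a
three-level model that addresses these jointly, for analysts running
food-item scans on cohort data and for methodologists studying shrinkage
estimators for count regression.

## The model

For subject *i* with total count *z*<sub>*i*</sub> and standardized food
score *x*<sub>*i*</sub>, and OTU *j*:

- **Counts:** Y<sub>ij</sub> ~ NB(μ<sub>ij</sub>, φ<sub>j</sub>) with
  log μ<sub>ij</sub> = α<sub>j</sub> + x<sub>i</sub>β<sub>j</sub> +
  log z<sub>i</sub>, and Var(Y) = μ + μ²/φ.
- **Phylogenetic shrinkage:** within each family *f*,
  (α<sub>j</sub>, β<sub>j</sub>) ~ N((μ<sub>αf</sub>, μ<sub>βf</sub>),
  Σ<sub>f</sub>), with family-specific scales and one intercept–slope
  correlation ω shared across families; family means get normal priors
  with N(0,1) / Exponential(1) hyperpriors.
- **Mean–dispersion regularization:** φ<sub>j</sub> ~
  Lognormal(a₁·μ̄<sub>j</sub> + a₀, σ<sub>φ</sub>²), where μ̄<sub>j</sub>
  is the OTU's average fitted mean — OTUs of similar abundance share
  dispersion information, which stabilizes the notoriously unstable
  per-OTU estimates.

Posterior inference uses a built-in No-U-Turn sampler (C++ core, analytic
gradients, block-diagonal metric adaptation); no external probabilistic
programming framework is required. Comparators (per-OTU `MASS::glm.nb`
and the same hierarchy without the phylogeny level), a simulation
framework with attached ground truth, estimator metrics (MSE, bias, 95%
interval coverage, FDR) and a cohort-style pipeline
(prevalence/family-size filtering, abundance-ordered batching,
Bonferroni-across-batches significance) are included. See the methods
vignette (`vignettes/dietbhm-methods.Rmd`) for the full model, priors,
sampler design and limitations.

## Worked example

Simulate a two-family dataset with a known diet effect (family 2 slope
mean +1, family 1 null), fit the model, and summarize associations:

```r
library(dietbhm)
sim  <- simulate_dataset(n_otu = 20, n_subj = 100, dispersion = "over",
                         seed = 42)
spec <- model_spec(chains = 2, warmup = 300, draws = 300, thin = 1, seed = 1)
fit  <- fit_bhm(sim$counts, sim$taxonomy, sim$covariate, spec)
tab  <- summarize_associations(fit)
head(tab[, c("otu_id", "family", "beta_mean", "beta_sd", "z",
             "ci_lower", "ci_upper", "significant")], 5)
```

```
  otu_id family beta_mean beta_sd     z ci_lower ci_upper significant
1 OTU001     f1     0.030   0.065  0.46   -0.083    0.180       FALSE
2 OTU002     f1     0.021   0.067  0.31   -0.104    0.159       FALSE
3 OTU003     f1    -0.047   0.063 -0.74   -0.203    0.072       FALSE
4 OTU004     f1     0.039   0.068  0.57   -0.075    0.165       FALSE
5 OTU005     f2     0.961   0.074 12.92    0.813    1.100        TRUE
```

The family-1 (null) OTUs sit near zero with intervals covering 0; the
family-2 OTU recovers its simulated slope near +1 and is flagged
significant. Comparing against the per-OTU maximum-likelihood fit on the
same data:

```r
glm <- fit_nb_glm(sim$counts, sim$covariate)
rbind(
  evaluate_slopes(tab$beta_mean, tab$ci_lower, tab$ci_upper,
                  tab$significant, sim$truth, method = "bhm"),
  evaluate_slopes(glm$beta_mean, glm$ci_lower, glm$ci_upper,
                  glm$significant, sim$truth, keep = glm$converged,
                  method = "glm.nb"))
```

```
  method     mse    bias coverage    fdr fdr_literal n_eval n_excluded
1    bhm 0.00749 -0.0552      0.9 0.0000          NA     20          0
2 glm.nb 0.01419 -0.0416      0.9 0.0833           9     20          0
```

The hierarchical fit roughly halves the slope MSE relative to independent
per-OTU regressions — the phylogenetic shrinkage at work.

A command-line interface covering `simulate`, `fit`, `glm`, `evaluate`
and `pipeline` is installed at `inst/scripts/dietbhm`:

```sh
Rscript inst/scripts/dietbhm simulate --n-otu 100 --n-subj 250 \
    --dispersion over --seed 1 --out-dir sim/
Rscript inst/scripts/dietbhm pipeline --counts sim/sim_counts.tsv \
    --taxonomy sim/sim_taxonomy.tsv --covariates sim/sim_covariate.tsv \
    --seed 1 --out associations.tsv
```

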