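---
title: "Hierarchical negative binomial models for diet-microbiome associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical negative binomial models for diet-microbiome associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cohort studies that collect both food-frequency questionnaires (FFQ) and
16S rRNA gut microbiome profiles ask, per food item and per OTU: does the
abundance of this organism change with consumption of this food? Three
features of OTU count tables make this hard: library sizes vary by orders
of magnitude across subjects, single-OTU counts are over-dispersed and
zero-rich, and OTUs are phylogenetically related, so close relatives tend
to respond similarly to diet. `dietbhm` addresses all three with one
three-level Bayesian model, fitted per food item.

## The model

For subject $i$ and OTU $j$, with total count $z_i$ and standardized food
score $x_i$:

**Level 1 (counts).**
$$Y_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi_j), \qquad
  \log \mu_{ij} = \alpha_j + x_i \beta_j + \log z_i,$$
with the mean-dispersion parameterization
$\mathrm{Var}(Y) = \mu + \mu^2/\phi$, so large $\phi$ approaches the
Poisson. The $\log z_i$ offset absorbs sequencing depth.

**Level 2 (phylogenetic shrinkage).** Within family $f$,
$$(\alpha_j, \beta_j) \sim \mathcal{N}\!\big(
   (\mu_{\alpha f}, \mu_{\beta f}), \Sigma_f \big), \qquad
  \Sigma_f = \begin{pmatrix}
    \sigma_{\alpha f}^2 & \omega \sigma_{\alpha f}\sigma_{\beta f} \\
    \omega \sigma_{\alpha f}\sigma_{\beta f} & \sigma_{\beta f}^2
  \end{pmatrix}.$$
The intercept-slope correlation $\omega$ is shared across families because
small families carry too little information to estimate their own.

**Level 3 (priors).**
$\mu_{\alpha f} \sim \mathcal{N}(\mu_\alpha, \sigma_\alpha^2)$,
$\mu_{\beta f} \sim \mathcal{N}(\mu_\beta, \sigma_\beta^2)$, with
$(\mu_\alpha, \mu_\beta) \sim \mathcal{N}(0, 1)$ and
$(\sigma_\alpha, \sigma_\beta) \sim \mathrm{Exponential}(1)$.

**Mean-dispersion regularization.** Dispersion estimates from sparse
counts are unstable, so information is shared between OTUs of similar
abundance:
$$\phi_j \sim \mathrm{Lognormal}(\mu_{\phi j},\, \sigma_\phi^2), \qquad
  \mu_{\phi j} = a_1 \cdot \tfrac{1}{N}\textstyle\sum_i \mu_{ij} + a_0,$$
with $(a_1, a_0) \sim \mathcal{N}(0,1)$ and
$\sigma_\phi \sim \mathrm{Exponential}(1)$. The trend location depends on
the *current* fitted means and is recomputed at every density evaluation,
not plugged in from a first pass.

Priors not pinned down elsewhere are package choices:
$\sigma_{\alpha f}, \sigma_{\beta f} \sim \mathrm{Exponential}(1)$
(mirroring the hyper-SD priors) and $\omega \sim \mathrm{Uniform}(-1, 1)$,
the flat proper choice for a single correlation.

## Posterior computation

The package ships its own No-U-Turn sampler (multinomial trajectory
sampling, dual-averaging step size targeting acceptance 0.8, windowed
metric adaptation) over a hand-derived joint log density and analytic
gradient implemented in C++. Defaults mirror common practice: 4 chains,
1,000 warm-up and 1,000 sampling iterations per chain, thinning 2 (500
stored draws per chain), maximum tree depth 10. Convergence is monitored
with split R-hat (threshold 1.05) and effective sample size; a fit that
crosses the threshold carries a recorded warning, never an error. The
sampler is generic: `nuts_sample()` accepts any R log-density/gradient
callback, which is how the test suite validates it against conjugate
closed forms.

Design choices that matter for sampling efficiency, all measured on the
simulation scenarios during development:

* **Centered coefficient parameterization by default.** With 50+ subjects
  the likelihood dominates the family prior, and a non-centered
  parameterization (standard-normal innovations scaled by the Cholesky of
  $\Sigma_f$) produces a funnel between innovations and family
  means/scales; mean tree depth reached 7-8. Evaluating the bivariate
  family prior directly on $(\alpha_j, \beta_j)$ samples at tree depth
  4-5. Both parameterizations are implemented (`model_spec(centered=)`),
  target identical densities (unit-tested via exact change-of-variable
  identities), and the non-centered variant remains preferable for very
  sparse data.
* **Internal covariate centering.** The likelihood is evaluated with
  $x - \bar x$ and the intercept at the covariate mean — a linear,
  unit-Jacobian reparameterization that removes the intercept-slope
  likelihood correlation. Reported intercepts are on the original scale.
* **Block-diagonal metric.** The adapted inverse metric uses 2x2 blocks
  for each per-OTU (intercept, slope) pair and for $(a_1, a_0)$, whose
  posterior correlation (induced by $\omega$, the covariate, and the
  near-collinearity of the dispersion trend) a diagonal metric cannot
  absorb.
* **Curvature-seeded metric and data-informed starts.** The metric is
  initialized from finite-difference diagonal curvature at the start
  point, and intercepts start at the empirical log mean relative count
  (slopes at zero, scales at one, everything jittered uniformly by 0.1
  per chain). Both choices only shorten warm-up; they do not change the
  target.
* **Positive parameters are sampled on the log scale** with Jacobian
  corrections, and $\omega$ via $\tanh$.

Likelihood evaluations use per-OTU recurrence tables for the
$\log\Gamma(\phi + y) - \log\Gamma(\phi)$ and digamma differences (exact
for counts up to 1024) and asymptotic series beyond, so a density+gradient
evaluation costs one `exp` and one `log` per count-matrix cell.

## The simulation framework

`simulate_dataset()` generates data from the two-family design used in the
package's validation study, with ground truth attached:

* two families assigned uniformly at random; family 1 has
  $(\mu_\alpha, \mu_\beta) = (2, 0)$, family 2 $(2, \pm 1)$ with the sign
  drawn per dataset; per-OTU coefficients are bivariate normal with SDs
  0.1 and correlation $-0.7$;
* food scores $x_i \sim \mathcal{N}(\mu_x, 1)$ with $\mu_x$ drawn from
  $\{0, +1, -1\}$; the skewed variant squares the scores (the SD of $x$
  is a package choice — the design names only the mean — and the offset
  is fixed at $z_i = 1$ so that parameter recovery is well defined);
* over-dispersed counts are negative binomial with
  $\phi_j \sim \mathrm{Lognormal}(0.1/\alpha_j,\, 0.1)$ (read as log-scale
  location and scale); under-dispersed counts are Poisson draws whose top
  20% per OTU are replaced, per dataset, either by the rounded per-OTU
  mean or by zero (zero inflation);
* the full grid crosses OTUs $\{10, 100, 200\}$, subjects
  $\{50, 250, 500\}$ and the two dispersion regimes into 18 scenarios;
  `run_grid()` enumerates it deterministically (100 replicates per
  scenario = 1,800 datasets, half of each scenario's replicates skewed).

What the generator does *not* emulate: real taxonomic family-size
distributions (two families only), compositionality and varying library
sizes ($z_i = 1$), covariate measurement error, or correlated food items.
Passing simulation tests therefore demonstrates correctness of the
machinery and the shrinkage behaviour under the model's own assumptions,
not performance on any particular cohort.

A known tail of the design: with skewed (squared) scores, $\mu_x = \pm 1$
and slope mean $+1$, counts reach $10^{10}$ and the average fitted means
of different OTUs span many orders of magnitude. The linear
mean-dispersion trend then ties $a_1$ to the largest-mean OTUs and the
posterior geometry degrades badly (this is a limitation of a trend that is
linear in the mean; a trend in $1/\bar\mu$ or $\log\bar\mu$ would not
suffer from it, but the linear form is the model specification). Such
datasets are exercised at small scale in the unit tests; the scaled-down
coverage study uses the standard-score variant.

## Performance evaluation

`mse()`, `bias()`, `coverage95()` and `fdr()` compare slope estimates with
the attached truth. FDR uses the standard ratio — false discoveries over
discoveries, zero when nothing is discovered — with "truly null" defined
as membership in the zero-mean-slope family (realized per-OTU slopes are
jittered around 0, so a strict-zero definition would be empty). The
literal ratio of nulls to false positives is also carried as a debugging
attribute, because its printed definition is ambiguous in places and the
standard quantity is the interpretable one. For Bayesian fits an OTU
counts as discovered when its 95% credible interval excludes 0; for the
GLM comparator, when the Wald p-value is below 0.05.

## The cohort-style pipeline

For real studies the workflow is: `filter_otus()` (keep OTUs with positive
counts in at least 20% of subjects, then keep OTUs whose identified family
still has at least 5 members; unclassified families are dropped),
`make_batches()` (families ordered by average relative abundance, packed
whole into batches of at most 200 OTUs; only oversized families are
split), then `run_food_item()` (one hierarchical fit per batch, offset =
log total counts, z-score significance threshold Bonferroni-corrected
across batches; within a batch the shrinkage itself is the multiplicity
control). Library sizes default to the *pre-filter* totals because the
offset represents sequencing depth, not the filtered subtotal
(`totals = "recompute"` gives the alternative). The greedy packing rule is
an interpretation — only the ordering by family abundance and the
never-split-unless-oversized behaviour are pinned down.

Batching is a memory/compute compromise: it truncates shrinkage for
families that are split, which is exactly where hierarchical information
is lost. The cap default (200) reflects what a single fit handles
comfortably.

## Scaled-down validation sizes

The packaged acceptance checks run the full machinery at reduced scale,
chosen as the smallest sizes at which the checked quantities are sharp:
coverage pools 400 intervals from 4 replicates of the (100 OTU, 250
subject) over-dispersed scenario with 4x(300 warm-up + 300 draws) chains
(Monte-Carlo SE of pooled coverage about 0.017 against an acceptance band
of [0.90, 0.99]); the method comparison uses 10 replicates with 2x(125 +
125) chains, which adds Monte-Carlo noise that is small relative to the
MSE differences being compared; recovery of the family slope means uses
one dataset each at 100 and 200 OTUs. `scripts/acceptance.R` recomputes
the same quantities at slightly smaller replicate counts and prints them
as JSON.

## Known limitations

* Univariate only: one food item per fit, no food patterns and no
  covariate adjustment (ethnicity, age, ...). Extension to multiple
  regression is mechanical but out of scope.
* The phylogeny enters only through the family grouping; genus and higher
  ranks, and uncertainty in the taxonomy itself, are ignored. A wrong
  family assignment biases that OTU's estimate toward the wrong average.
* About 200 OTUs fit comfortably in one batch; larger sets are split,
  which weakens shrinkage for the split families.
* The linear mean-dispersion trend degrades on data whose fitted means
  span many orders of magnitude (see above).
* Under-dispersed (zero-inflated Poisson-like) data push $\phi_j$ to very
  large values; the model remains fittable but interval coverage is known
  to drop below nominal there — the regularization trades this regime for
  stability in the common over-dispersed one.
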