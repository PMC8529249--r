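#' Sampler and model settings
#'
#' Bundles all tunable settings of the hierarchical model fit. The defaults
#' are the settings used throughout: 4 chains, 1,000 warm-up iterations and
#' 1,000 post-warm-up iterations per chain with a thinning of two (500
#' stored draws per chain).
#'
#' @param use_phylogeny use the phylogenetic-family level (`TRUE`) or pool
#'   all OTUs into a single group (`FALSE`).
#' @param chains number of MCMC chains.
#' @param warmup warm-up (adaptation) iterations per chain.
#' @param draws post-warm-up iterations per chain; `draws %/% thin` draws
#'   are stored.
#' @param thin thinning interval.
#' @param seed integer seed; all chain seeds derive from it.
#' @param max_treedepth maximum trajectory doubling depth of the sampler.
#' @param adapt_delta target acceptance statistic for step-size adaptation.
#' @param init_jitter half-width of the uniform jitter applied to the
#'   (zero) initial values of each chain on the unconstrained scale.
#' @param rhat_threshold split R-hat above which a convergence warning is
#'   recorded in the fit.
#' @param centered parameterization flag: sample per-OTU intercepts and
#'   slopes directly (`TRUE`, default; well suited when the likelihood is
#'   informative) or as standard-normal innovations scaled by the family
#'   covariance (`FALSE`, the classic non-centered variant for sparse
#'   data). Both target the same joint density.
#' @return A list of class `bhm_spec`.
#' @export
model_spec <- function(use_phylogeny = TRUE, chains = 4, warmup = 1000,
                       draws = 1000, thin = 2, seed = 1, max_treedepth = 10,
                       adapt_delta = 0.8, init_jitter = 0.1,
                       rhat_threshold = 1.05, centered = TRUE) {
  stopifnot(chains >= 1, warmup >= 0, draws >= 1, thin >= 1,
            max_treedepth >= 1, adapt_delta > 0, adapt_delta < 1)
  structure(list(use_phylogeny = isTRUE(use_phylogeny),
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), thin = as.integer(thin),
                 seed = as.integer(seed),
                 max_treedepth = as.integer(max_treedepth),
                 adapt_delta = adapt_delta, init_jitter = init_jitter,
                 rhat_threshold = rhat_threshold,
                 centered = isTRUE(centered)),
            class = "bhm_spec")
}

#' Read model settings from a YAML (or flat key-value) config file
#'
#' Keys mirror the arguments of [model_spec()]; unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return A `bhm_spec`.
#' @export
model_spec_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(model_spec))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(model_spec, cfg)
}

#' Negative binomial log pmf (mean-dispersion parameterization)
#'
#' Log probability mass of the negative binomial with mean `mu` and
#' dispersion `phi`, so that `Var(Y) = mu + mu^2 / phi`; as `phi` grows the
#' distribution approaches the Poisson with mean `mu`.
#'
#' @param y non-negative integer counts.
#' @param mu positive mean.
#' @param phi positive dispersion.
#' @return Log pmf values, vectorized over the arguments.
#' @export
nb_log_pmf <- function(y, mu, phi) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be positive")
  if (any(!is.finite(phi)) || any(phi <= 0)) stop("phi must be positive")
  if (any(y < 0) || any(y != round(y)))
    stop("y must be a non-negative integer")
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    phi * (log(phi) - log(phi + mu)) + y * (log(mu) - log(phi + mu))
}

#' Negative binomial mean from the linear predictor with offset
#'
#' Evaluates `mu = exp(alpha + x * beta + log(z))`, the model mean for one
#' subject and OTU; `z` is the subject's total count (sequencing depth).
#'
#' @param alpha intercept (log scale).
#' @param beta slope per unit of the covariate.
#' @param x covariate value.
#' @param z positive offset (total count).
#' @return The positive mean, vectorized over the arguments.
#' @export
linear_predictor <- function(alpha, beta, x, z) {
  if (any(!is.finite(z)) || any(z <= 0)) stop("offset z must be positive")
  exp(alpha + x * beta + log(z))
}

#' Location of the mean-dispersion trend
#'
#' The lognormal prior location for the dispersion of an OTU is a linear
#' function `a1 * m + a0` of the OTU's average fitted mean `m` across
#' subjects, sharing dispersion information between OTUs of similar
#' abundance.
#'
#' @param mu_row_mean average of the fitted means of one OTU over subjects.
#' @param a1,a0 trend slope and intercept.
#' @return The trend location (log scale of the dispersion).
#' @export
dispersion_trend_location <- function(mu_row_mean, a1, a0) {
  a1 * mu_row_mean + a0
}

# bivariate normal log density with means m, sds s, correlation w
.dbvnorm_log <- function(x1, x2, m1, m2, s1, s2, w) {
  d1 <- (x1 - m1) / s1
  d2 <- (x2 - m2) / s2
  -log(2 * pi) - log(s1) - log(s2) - 0.5 * log1p(-w^2) -
    (d1^2 - 2 * w * d1 * d2 + d2^2) / (2 * (1 - w^2))
}

#' Joint log density of the hierarchical model (natural parameterization)
#'
#' Reference evaluation of the full three-level joint density at a given
#' parameter state: negative binomial likelihood, bivariate-normal family
#' shrinkage of intercepts and slopes, normal family-mean priors, the
#' mean-dispersion lognormal prior and all hyperpriors. This is the density
#' the sampler targets (the sampler works on an unconstrained
#' reparameterization of the same density).
#'
#' @param state named list with elements `mu_alpha`, `mu_beta`,
#'   `sigma_alpha`, `sigma_beta`, `mu_alpha_f`, `mu_beta_f`,
#'   `sigma_alpha_f`, `sigma_beta_f` (length number of families), `omega`,
#'   `alpha`, `beta`, `phi` (length number of OTUs), `a1`, `a0`,
#'   `sigma_phi`.
#' @param counts a [count_matrix].
#' @param fam a [family_map] covering the OTUs of `counts` (ignored with a
#'   single pooled family when `use_phylogeny` is `FALSE`).
#' @param x a [covariate_vector] or numeric vector aligned with subjects.
#' @param use_phylogeny collapse to a single family when `FALSE`.
#' @return The joint log density (scalar), with attribute `"terms"` giving
#'   the likelihood, level-2, level-3 and hyperprior contributions.
#' @export
joint_log_density <- function(state, counts, fam, x, use_phylogeny = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  xv <- if (inherits(x, "covariate_vector")) x$x else as.numeric(x)
  dat <- .align_model_data(counts, fam, xv, use_phylogeny)
  J <- length(dat$fam_index)
  Ff <- length(dat$fam_levels)
  s <- state
  .check_pos <- function(v, nm) {
    if (any(!is.finite(v)) || any(v <= 0))
      stop(nm, " must be strictly positive")
  }
  .check_pos(s$sigma_alpha, "sigma_alpha"); .check_pos(s$sigma_beta, "sigma_beta")
  .check_pos(s$sigma_alpha_f, "sigma_alpha_f"); .check_pos(s$sigma_beta_f, "sigma_beta_f")
  .check_pos(s$sigma_phi, "sigma_phi"); .check_pos(s$phi, "phi")
  if (abs(s$omega) >= 1) stop("omega must lie in (-1, 1)")
  stopifnot(length(s$alpha) == J, length(s$beta) == J, length(s$phi) == J,
            length(s$mu_alpha_f) == Ff, length(s$mu_beta_f) == Ff)

  eta <- outer(dat$logz, s$alpha, "+") + outer(xv, s$beta)
  mu <- exp(eta)
  ll <- sum(nb_log_pmf(dat$Y, mu, rep(s$phi, each = nrow(dat$Y))))

  fi <- dat$fam_index
  lev2 <- sum(.dbvnorm_log(s$alpha, s$beta,
                           s$mu_alpha_f[fi], s$mu_beta_f[fi],
                           s$sigma_alpha_f[fi], s$sigma_beta_f[fi], s$omega))
  lev3 <- sum(dnorm(s$mu_alpha_f, s$mu_alpha, s$sigma_alpha, log = TRUE)) +
    sum(dnorm(s$mu_beta_f, s$mu_beta, s$sigma_beta, log = TRUE))
  m_j <- colMeans(mu)
  mu_phi <- dispersion_trend_location(m_j, s$a1, s$a0)
  disp <- sum(stats::dlnorm(s$phi, mu_phi, s$sigma_phi, log = TRUE))
  hyper <- dnorm(s$mu_alpha, 0, 1, log = TRUE) +
    dnorm(s$mu_beta, 0, 1, log = TRUE) +
    stats::dexp(s$sigma_alpha, 1, log = TRUE) +
    stats::dexp(s$sigma_beta, 1, log = TRUE) +
    sum(stats::dexp(s$sigma_alpha_f, 1, log = TRUE)) +
    sum(stats::dexp(s$sigma_beta_f, 1, log = TRUE)) +
    stats::dunif(s$omega, -1, 1, log = TRUE) +
    dnorm(s$a1, 0, 1, log = TRUE) + dnorm(s$a0, 0, 1, log = TRUE) +
    stats::dexp(s$sigma_phi, 1, log = TRUE)
  total <- ll + lev2 + lev3 + disp + hyper
  attr(total, "terms") <- c(likelihood = ll, family_level = lev2,
                            family_means = lev3, dispersion = disp,
                            hyperpriors = hyper)
  total
}

# Align counts / taxonomy / covariate into the internal model inputs.
# Returns Y (N x J), logz, x, fam_index (1-based), fam_levels, otu_ids.
.align_model_data <- function(counts, fam, x, use_phylogeny = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  otu_ids <- counts$otu_ids
  if (use_phylogeny) {
    if (is.null(fam)) stop("a family map is required when use_phylogeny = TRUE")
    if (!inherits(fam, "family_map")) fam <- family_map(names(fam), fam)
    idx <- match(otu_ids, fam$otu_id)
    if (anyNA(idx))
      stop("OTU(s) missing from the family map: ",
           paste(otu_ids[is.na(idx)][seq_len(min(3, sum(is.na(idx))))],
                 collapse = ", "))
    labels <- fam$family[idx]
  } else {
    labels <- rep("all", length(otu_ids))
  }
  fac <- factor(labels, levels = unique(labels))
  if (length(x) != nrow(counts$counts))
    stop("covariate length does not match the number of subjects")
  list(Y = counts$counts, logz = log(counts$totals), x = as.numeric(x),
       fam_index = as.integer(fac), fam_levels = levels(fac),
       otu_ids = otu_ids)
}

#' Unconstrained-scale log posterior and gradient
#'
#' Evaluates the log posterior density targeted by the sampler (including
#' all change-of-variable Jacobians of the unconstrained
#' parameterization) and its analytic gradient. Mostly of interest for
#' validating the gradient and for plugging alternative samplers in.
#'
#' @param theta unconstrained parameter vector (see [bhm_param_layout()]).
#' @param centered parameterization of the per-OTU coefficient block (see
#'   [model_spec()]).
#' @inheritParams joint_log_density
#' @return List with elements `lp` and `grad`.
#' @export
bhm_lp_grad <- function(theta, counts, fam, x, use_phylogeny = TRUE,
                        centered = TRUE) {
  xv <- if (inherits(x, "covariate_vector")) x$x else as.numeric(x)
  dat <- .align_model_data(counts, fam, xv, use_phylogeny)
  cpp_bhm_lp_grad(theta, dat$Y, dat$x, dat$logz, dat$fam_index,
                  length(dat$fam_levels), centered)
}

#' Layout of the unconstrained parameter vector
#'
#' @param n_otu number of OTUs.
#' @param n_family number of families.
#' @param centered parameterization flag (see [model_spec()]).
#' @return Character vector of parameter names in the order used by the
#'   unconstrained parameter vector of the sampler.
#' @export
bhm_param_layout <- function(n_otu, n_family, centered = TRUE) {
  J <- n_otu; Ff <- n_family
  coef_block <- if (centered)
    c(paste0("alpha[", seq_len(J), "]"), paste0("beta[", seq_len(J), "]"))
  else
    c(paste0("u1[", seq_len(J), "]"), paste0("u2[", seq_len(J), "]"))
  c("mu_alpha", "mu_beta", "log_sigma_alpha", "log_sigma_beta",
    paste0("mu_alpha_f[", seq_len(Ff), "]"),
    paste0("mu_beta_f[", seq_len(Ff), "]"),
    paste0("log_sigma_alpha_f[", seq_len(Ff), "]"),
    paste0("log_sigma_beta_f[", seq_len(Ff), "]"),
    "atanh_omega", coef_block,
    "a1", "a0", "log_sigma_phi",
    paste0("log_phi[", seq_len(J), "]"))
}

# Map a natural-scale state (as for joint_log_density) to the unconstrained
# vector used by the sampler. In the centered parameterization the
# intercept block holds the intercept at the covariate mean.
.bhm_unconstrain <- function(state, fam_index, centered = TRUE, xbar = 0) {
  s <- state
  if (centered) {
    c1 <- s$alpha + xbar * s$beta
    c2 <- s$beta
  } else {
    saf <- s$sigma_alpha_f[fam_index]
    sbf <- s$sigma_beta_f[fam_index]
    c1 <- (s$alpha - s$mu_alpha_f[fam_index]) / saf
    v <- (s$beta - s$mu_beta_f[fam_index]) / sbf
    comp <- sqrt(1 - s$omega^2)
    c2 <- (v - s$omega * c1) / comp
  }
  c(s$mu_alpha, s$mu_beta, log(s$sigma_alpha), log(s$sigma_beta),
    s$mu_alpha_f, s$mu_beta_f, log(s$sigma_alpha_f), log(s$sigma_beta_f),
    atanh(s$omega), c1, c2, s$a1, s$a0, log(s$sigma_phi), log(s$phi))
}
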