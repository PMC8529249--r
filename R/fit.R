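#' Fit the Bayesian hierarchical negative binomial model
#'
#' Fits the three-level model: a negative binomial likelihood with log link
#' and log total-count offset per OTU; bivariate-normal shrinkage of
#' per-OTU intercepts and slopes toward phylogenetic-family averages with a
#' shared intercept-slope correlation; normal/exponential hyperpriors; and
#' a lognormal prior on each OTU's dispersion whose location follows a
#' linear trend in the OTU's average fitted mean. Posterior draws are
#' produced by the built-in No-U-Turn sampler with analytic gradients.
#'
#' @param counts a [count_matrix] (at least 2 subjects).
#' @param fam a [family_map]; ignored when `spec$use_phylogeny` is `FALSE`.
#' @param x a [covariate_vector] or numeric vector aligned with the
#'   subjects of `counts`.
#' @param spec a [model_spec()].
#' @param food_item label for the covariate in association tables;
#'   defaults to the covariate's name.
#' @return An object of class `bhm_fit` with posterior draws (stored
#'   iterations x chains x parameters, natural scale), per-parameter
#'   summaries with split R-hat and effective sample size, and sampler
#'   diagnostics. A convergence warning (any split R-hat above
#'   `spec$rhat_threshold`) is recorded in `$warnings`, not thrown.
#' @seealso [fit_bhm_nophylo()], [summarize_associations()]
#' @export
fit_bhm <- function(counts, fam, x, spec = model_spec(), food_item = NULL) {
  stopifnot(inherits(spec, "bhm_spec"))
  if (nrow(counts$counts) < 2) stop("need at least 2 subjects")
  xv <- if (inherits(x, "covariate_vector")) x$x else as.numeric(x)
  if (is.null(food_item))
    food_item <- if (inherits(x, "covariate_vector")) x$name else "x"
  dat <- .align_model_data(counts, fam, xv, spec$use_phylogeny)
  J <- length(dat$otu_ids)
  Ff <- length(dat$fam_levels)
  P <- 4 + 4 * Ff + 1 + 2 * J + 3 + J
  centered <- !isFALSE(spec$centered)
  runner <- function(chain_init) {
    cpp_nuts_bhm(dat$Y, dat$x, dat$logz, dat$fam_index, Ff, chain_init,
                 spec$warmup, spec$draws, spec$thin, spec$max_treedepth,
                 spec$adapt_delta, centered)
  }
  init <- .bhm_init(dat, J, Ff, centered)
  raw <- .run_chains(runner, init, spec$chains, spec$warmup,
                     spec$draws, spec$thin, spec$seed, spec$init_jitter, P)
  .build_bhm_fit(raw, dat, spec, food_item)
}

# Initial values: intercepts at the empirical log mean relative count
# (slopes zero, scales 1, correlation 0), which places the chains near the
# bulk of the likelihood and shortens warmup considerably compared to an
# all-zero start. Each chain jitters these values (see model_spec).
.bhm_init <- function(dat, J, Ff, centered) {
  P <- 4 + 4 * Ff + 1 + 2 * J + 3 + J
  ap0 <- log((colSums(dat$Y) + 0.5) / sum(exp(dat$logz)))
  muaf0 <- as.numeric(tapply(ap0, dat$fam_index, mean))[seq_len(Ff)]
  init <- rep(0, P)
  init[1] <- mean(ap0)
  init[4 + seq_len(Ff)] <- muaf0
  c1 <- if (centered) ap0 else ap0 - muaf0[dat$fam_index]
  init[4 + 4 * Ff + 1 + seq_len(J)] <- c1
  init
}

#' Fit the hierarchical model without the phylogenetic level
#'
#' Identical to [fit_bhm()] with all OTUs pooled into a single group, so
#' that every intercept and slope is shrunk toward one common bivariate
#' normal mean; the mean-dispersion regularization is retained.
#'
#' @inheritParams fit_bhm
#' @return A `bhm_fit`.
#' @export
fit_bhm_nophylo <- function(counts, fam = NULL, x, spec = model_spec(),
                            food_item = NULL) {
  spec$use_phylogeny <- FALSE
  fit <- fit_bhm(counts, fam = NULL, x = x, spec = spec,
                 food_item = food_item)
  fit
}

# assemble the bhm_fit object: constrain draws, summaries, diagnostics
.build_bhm_fit <- function(raw, dat, spec, food_item) {
  J <- length(dat$otu_ids)
  Ff <- length(dat$fam_levels)
  S <- dim(raw$draws)[1]
  C <- dim(raw$draws)[2]
  cn <- .constrained_names(dat$otu_ids, dat$fam_levels)
  K <- length(cn)
  cd <- array(NA_real_, c(S, C, K), dimnames = list(NULL, NULL, cn))
  for (ch in seq_len(C))
    cd[, ch, ] <- .constrain_draws(raw$draws[, ch, , drop = TRUE], J, Ff,
                                   dat$fam_index,
                                   centered = !isFALSE(spec$centered),
                                   xbar = mean(dat$x))
  dg <- mcmc_diagnostics(cd)
  qs <- apply(cd, 3, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  summ <- data.frame(
    parameter = cn,
    mean = apply(cd, 3, mean), sd = apply(cd, 3, sd),
    q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
    rhat = dg$rhat, ess = dg$ess,
    row.names = NULL, stringsAsFactors = FALSE)
  max_rhat <- suppressWarnings(max(summ$rhat, na.rm = TRUE))
  n_div <- sum(vapply(raw$chains, function(d) d$n_divergent, numeric(1)))
  warnings <- character(0)
  if (is.finite(max_rhat) && max_rhat > spec$rhat_threshold)
    warnings <- c(warnings, sprintf(
      "convergence: max split R-hat %.3f exceeds %.2f", max_rhat,
      spec$rhat_threshold))
  if (n_div > 0)
    warnings <- c(warnings,
                  sprintf("%d divergent transitions after warmup", n_div))
  structure(list(
    draws = cd, lp = raw$lp, summary = summ,
    otu_ids = dat$otu_ids, family = dat$fam_levels[dat$fam_index],
    family_levels = dat$fam_levels, food_item = food_item,
    n_subjects = nrow(dat$Y), spec = spec, sampler = raw$chains,
    max_rhat = max_rhat, n_divergent = n_div,
    converged = !length(warnings), warnings = warnings),
    class = "bhm_fit")
}

.constrained_names <- function(otu_ids, fam_levels) {
  c("mu_alpha", "mu_beta", "sigma_alpha", "sigma_beta",
    paste0("mu_alpha_f[", fam_levels, "]"),
    paste0("mu_beta_f[", fam_levels, "]"),
    paste0("sigma_alpha_f[", fam_levels, "]"),
    paste0("sigma_beta_f[", fam_levels, "]"),
    "omega",
    paste0("alpha[", otu_ids, "]"),
    paste0("beta[", otu_ids, "]"),
    paste0("phi[", otu_ids, "]"),
    "a1", "a0", "sigma_phi")
}

# unconstrained draw matrix (S x P) -> constrained matrix (S x K);
# in the centered parameterization the sampler works with the intercept at
# the covariate mean, so the reported intercept is u1 - xbar * u2
.constrain_draws <- function(u, J, Ff, fam_index, centered = TRUE,
                             xbar = 0) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  i <- 0
  take <- function(n) {
    cols <- u[, i + seq_len(n), drop = FALSE]
    i <<- i + n
    cols
  }
  mua <- take(1); mub <- take(1)
  sa <- exp(take(1)); sb <- exp(take(1))
  muaf <- take(Ff); mubf <- take(Ff)
  saf <- exp(take(Ff)); sbf <- exp(take(Ff))
  omega <- tanh(take(1))
  u1 <- take(J); u2 <- take(J)
  a1 <- take(1); a0 <- take(1)
  sphi <- exp(take(1))
  phi <- exp(take(J))
  if (centered) {
    alpha <- u1 - xbar * u2
    beta <- u2
  } else {
    comp <- sqrt(1 - omega^2)
    alpha <- muaf[, fam_index, drop = FALSE] +
      saf[, fam_index, drop = FALSE] * u1
    beta <- mubf[, fam_index, drop = FALSE] +
      sbf[, fam_index, drop = FALSE] *
        (omega[, 1] * u1 + comp[, 1] * u2)
  }
  cbind(mua, mub, sa, sb, muaf, mubf, saf, sbf, omega, alpha, beta, phi,
        a1, a0, sphi)
}

#' Extract posterior draws of selected parameters
#'
#' @param fit a `bhm_fit`.
#' @param pars parameter names (as in `fit$summary$parameter`), or a prefix
#'   such as `"beta"` to select all indexed parameters of that name.
#' @return Matrix of draws (all chains pooled) with one column per
#'   parameter.
#' @export
posterior_draws <- function(fit, pars) {
  stopifnot(inherits(fit, "bhm_fit"))
  all <- dimnames(fit$draws)[[3]]
  sel <- unlist(lapply(pars, function(p) {
    if (p %in% all) return(p)
    hit <- all[startsWith(all, paste0(p, "["))]
    if (length(hit) == 0) stop("no parameter matching '", p, "'")
    hit
  }))
  S <- dim(fit$draws)[1]; C <- dim(fit$draws)[2]
  out <- matrix(fit$draws[, , sel], S * C, length(sel))
  colnames(out) <- sel
  out
}

#' @export
print.bhm_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian hierarchical NB fit: %d OTUs, %d subjects, %d famil%s\n",
    length(x$otu_ids), x$n_subjects, length(x$family_levels),
    if (length(x$family_levels) == 1) "y" else "ies"))
  cat(sprintf("  chains %d, warmup %d, draws %d (thin %d), seed %d\n",
              x$spec$chains, x$spec$warmup, x$spec$draws, x$spec$thin,
              x$spec$seed))
  cat(sprintf("  max split R-hat %.3f; divergent transitions %d\n",
              x$max_rhat, x$n_divergent))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  hyper <- x$summary[x$summary$parameter %in%
                       c("mu_alpha", "mu_beta", "omega", "a1", "a0",
                         "sigma_phi"), ]
  print(hyper, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Summarize per-OTU diet-microbe associations
#'
#' Per-OTU posterior summary of the slope: posterior mean and SD, the
#' z-score (mean divided by SD), the central 95% credible interval and a
#' significance flag. The significance threshold is Bonferroni-corrected
#' for the number of batches the OTU set was analyzed in:
#' `|z| > qnorm(1 - 0.05 / (2 * n_batches))`.
#'
#' @param fit a `bhm_fit`.
#' @param n_batches number of batches over which to Bonferroni-correct
#'   (1 gives the usual two-sided 5% threshold of 1.96).
#' @return Data frame with columns `otu_id`, `family`, `food_item`,
#'   `beta_mean`, `beta_sd`, `z`, `ci_lower`, `ci_upper`, `rhat`, `ess`,
#'   `significant`.
#' @export
summarize_associations <- function(fit, n_batches = 1) {
  stopifnot(inherits(fit, "bhm_fit"))
  if (n_batches < 1) stop("n_batches must be at least 1")
  thr <- qnorm(1 - 0.05 / (2 * n_batches))
  idx <- match(paste0("beta[", fit$otu_ids, "]"), fit$summary$parameter)
  s <- fit$summary[idx, ]
  z <- ifelse(s$sd > 0, s$mean / s$sd, sign(s$mean) * Inf)
  data.frame(
    otu_id = fit$otu_ids, family = fit$family, food_item = fit$food_item,
    beta_mean = s$mean, beta_sd = s$sd, z = z,
    ci_lower = s$q2.5, ci_upper = s$q97.5,
    rhat = s$rhat, ess = s$ess,
    significant = !is.na(z) & abs(z) > thr,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an association table as TSV
#'
#' @param tab data frame as returned by [summarize_associations()] or
#'   [fit_nb_glm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
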