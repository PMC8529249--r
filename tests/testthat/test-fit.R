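test_that("fit_bhm returns a coherent posterior object", {
  sim <- simulate_dataset(10, 40, "over", seed = 5)
  fit <- fit_bhm(sim$counts, sim$taxonomy, sim$covariate,
                 tiny_spec(seed = 11, thin = 3))
  expect_s3_class(fit, "bhm_fit")
  # stored draws per chain = draws %/% thin
  expect_equal(dim(fit$draws)[1], 150L %/% 3L)
  expect_equal(dim(fit$draws)[2], 2L)
  s <- fit$summary
  expect_true(all(s$q2.5 <= s$mean + 1e-8 & s$mean <= s$q97.5 + 1e-8))
  expect_equal(sum(startsWith(s$parameter, "beta[")), 10)
  expect_equal(sum(startsWith(s$parameter, "phi[")), 10)
  expect_true(all(s$parameter[startsWith(s$parameter, "phi[")] %in%
                    s$parameter[s$mean > 0]))
  expect_true(all(abs(s$mean[s$parameter == "omega"]) < 1))
  expect_true(is.finite(fit$max_rhat))
  expect_output(print(fit), "hierarchical NB fit")
})

test_that("fits are reproducible from the seed", {
  sim <- simulate_dataset(8, 30, "over", seed = 6)
  f1 <- fit_bhm(sim$counts, sim$taxonomy, sim$covariate,
                model_spec(chains = 2, warmup = 80, draws = 80, thin = 1,
                           seed = 21))
  f2 <- fit_bhm(sim$counts, sim$taxonomy, sim$covariate,
                model_spec(chains = 2, warmup = 80, draws = 80, thin = 1,
                           seed = 21))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_bhm(sim$counts, sim$taxonomy, sim$covariate,
                model_spec(chains = 2, warmup = 80, draws = 80, thin = 1,
                           seed = 22))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("fit without phylogeny equals a one-family fit", {
  sim <- simulate_dataset(8, 30, "over", seed = 8)
  one_fam <- family_map(sim$counts$otu_ids, rep("all", 8))
  spec <- model_spec(chains = 1, warmup = 100, draws = 100, thin = 1,
                     seed = 13)
  f_np <- fit_bhm_nophylo(sim$counts, x = sim$covariate, spec = spec)
  f_1f <- fit_bhm(sim$counts, one_fam, sim$covariate, spec = spec)
  expect_equal(unname(f_np$draws[, , "mu_beta_f[all]"]),
               unname(f_1f$draws[, , "mu_beta_f[all]"]))
  expect_equal(dimnames(f_np$draws)[[3]][5], "mu_alpha_f[all]")
})

test_that("the non-centered parameterization targets the same posterior", {
  sim <- simulate_dataset(8, 60, "over", seed = 19)
  sc <- model_spec(chains = 2, warmup = 250, draws = 350, thin = 1,
                   seed = 3, centered = TRUE)
  sn <- model_spec(chains = 2, warmup = 250, draws = 350, thin = 1,
                   seed = 3, centered = FALSE)
  fc <- fit_bhm(sim$counts, sim$taxonomy, sim$covariate, sc)
  fn <- fit_bhm(sim$counts, sim$taxonomy, sim$covariate, sn)
  bc <- posterior_draws(fc, "beta")
  bn <- posterior_draws(fn, "beta")
  # posterior means agree within combined Monte-Carlo error
  dgc <- fc$summary[match(colnames(bc), fc$summary$parameter), ]
  mc_se <- dgc$sd / sqrt(pmax(dgc$ess, 5))
  expect_true(all(abs(colMeans(bc) - colMeans(bn)) < 6 * mc_se + 0.02))
})

test_that("association summaries apply the Bonferroni z threshold", {
  sim <- simulate_dataset(6, 25, "over", seed = 9)
  fit <- fit_bhm(sim$counts, sim$taxonomy, sim$covariate,
                 model_spec(chains = 1, warmup = 80, draws = 100, thin = 1,
                            seed = 2))
  tab <- summarize_associations(fit, n_batches = 6)
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("otu_id", "family", "food_item", "beta_mean",
                      "beta_sd", "z", "ci_lower", "ci_upper", "rhat",
                      "ess", "significant"))
  expect_error(summarize_associations(fit, n_batches = 0), "n_batches")

  # synthetic fit: z just above/below the two thresholds
  fake <- fit
  idx <- startsWith(fake$summary$parameter, "beta[")
  fake$summary$mean[idx] <- c(2.5, 2.7, -2.5, -2.7, 0.5, 3.5)
  fake$summary$sd[idx] <- 1
  t1 <- summarize_associations(fake, n_batches = 1) # threshold 1.960
  t6 <- summarize_associations(fake, n_batches = 6) # threshold ~2.638
  expect_equal(t1$significant, c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(t6$significant, c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  # degenerate draws: sd 0, nonzero mean -> infinite z, flagged significant
  fake$summary$sd[idx][1] <- 0
  td <- summarize_associations(fake, n_batches = 1)
  expect_true(is.infinite(td$z[1]) && td$significant[1])
})

test_that("posterior_draws selects by name and prefix", {
  sim <- simulate_dataset(5, 20, "over", seed = 10)
  fit <- fit_bhm(sim$counts, sim$taxonomy, sim$covariate,
                 model_spec(chains = 1, warmup = 60, draws = 60, thin = 1,
                            seed = 2))
  d <- posterior_draws(fit, c("omega", "beta"))
  expect_equal(ncol(d), 1 + 5)
  expect_error(posterior_draws(fit, "nope"), "no parameter")
})

test_that("a small under-dispersed dataset fits without error", {
  sim <- simulate_dataset(6, 30, "under", seed = 12)
  fit <- fit_bhm(sim$counts, sim$taxonomy, sim$covariate,
                 model_spec(chains = 1, warmup = 100, draws = 100, thin = 1,
                            seed = 4))
  phis <- posterior_draws(fit, "phi")
  expect_true(all(is.finite(phis)))
  # Poisson-like data push dispersions up
  expect_gt(median(phis), 1)
})

test_that("skewed covariates at small scale fit without error", {
  sim <- simulate_dataset(10, 50, "over", skew_x = TRUE, seed = 14)
  fit <- fit_bhm(sim$counts, sim$taxonomy, sim$covariate,
                 model_spec(chains = 1, warmup = 120, draws = 120, thin = 1,
                            seed = 4))
  expect_true(all(is.finite(posterior_draws(fit, "beta"))))
})
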