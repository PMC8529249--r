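test_that("nb_log_pmf matches closed forms and an integration oracle", {
  # P(0) = (phi/(phi+mu))^phi
  expect_equal(nb_log_pmf(0, 1, 1), log(0.5), tolerance = 1e-12)
  # gamma-Poisson mixture evaluated by numerical integration
  mix_pmf <- function(y, mu, phi) {
    stats::integrate(function(l) stats::dpois(y, l) *
                       stats::dgamma(l, shape = phi, rate = phi / mu),
                     0, Inf, rel.tol = 1e-12)$value
  }
  expect_equal(nb_log_pmf(2, 3, 5), log(mix_pmf(2, 3, 5)), tolerance = 1e-9)
  expect_equal(nb_log_pmf(7, 2.5, 0.4), log(mix_pmf(7, 2.5, 0.4)),
               tolerance = 1e-9)
  # independent implementation in stats
  y <- c(0, 1, 4, 30, 1500)
  expect_equal(nb_log_pmf(y, 12, 0.7),
               dnbinom(y, size = 0.7, mu = 12, log = TRUE),
               tolerance = 1e-10)
})

test_that("nb_log_pmf approaches the Poisson limit for large dispersion", {
  expect_equal(nb_log_pmf(4, 2, 1e8), dpois(4, 2, log = TRUE),
               tolerance = 1e-4)
  expect_equal(nb_log_pmf(0:20, 6, 1e8), dpois(0:20, 6, log = TRUE),
               tolerance = 1e-4)
})

test_that("nb_log_pmf normalizes and matches the stated variance", {
  for (par in list(c(2, 0.5), c(10, 3), c(0.3, 8))) {
    mu <- par[1]; phi <- par[2]
    ymax <- ceiling(mu + 40 * sqrt(mu + mu^2 / phi)) + 200
    total <- sum(exp(nb_log_pmf(0:ymax, mu, phi)))
    expect_lt(abs(1 - total), 1e-6)
  }
  set.seed(11)
  mu <- 5; phi <- 2
  draws <- rnbinom(1e5, size = phi, mu = mu)
  v <- mu + mu^2 / phi
  se <- sd((draws - mean(draws))^2) / sqrt(1e5)
  expect_lt(abs(var(draws) - v), 3 * se)
})

test_that("nb_log_pmf and linear_predictor reject invalid domains", {
  expect_error(nb_log_pmf(1, -1, 1), "mu")
  expect_error(nb_log_pmf(1, 1, 0), "phi")
  expect_error(nb_log_pmf(1.5, 1, 1), "integer")
  expect_error(linear_predictor(0, 0, 0, 0), "positive")
  expect_equal(linear_predictor(2, 0.5, 1, 1), exp(2.5))
  expect_equal(linear_predictor(1.3, 0, 99, 7), exp(1.3) * 7)
  expect_equal(linear_predictor(0, 0, 0, 100), 100)
})

test_that("dispersion trend location is the stated linear function", {
  expect_equal(dispersion_trend_location(123, 0, 0), 0)
  expect_equal(dispersion_trend_location(20, 0.1, -1), 1)
  expect_equal(dispersion_trend_location(7.5, 1, 0), 7.5)
})

test_that("joint log density equals the sum of independently computed terms", {
  # single OTU, single subject, all-zero count: every term is hand-summable
  cm <- count_matrix(matrix(0L, 1, 1, dimnames = list("s1", "o1")),
                     totals = 4)
  fm <- family_map("o1", "famA")
  st <- list(mu_alpha = 0.2, mu_beta = -0.1, sigma_alpha = 0.7,
             sigma_beta = 1.1, mu_alpha_f = 1.5, mu_beta_f = 0.3,
             sigma_alpha_f = 0.2, sigma_beta_f = 0.3, omega = 0.4,
             alpha = 1.4, beta = 0.25, phi = 0.8, a1 = 0.6, a0 = -0.4,
             sigma_phi = 0.9)
  x <- 0.5
  lp <- joint_log_density(st, cm, fm, x)

  mu <- exp(st$alpha + st$beta * x + log(4))
  term_lik <- dnbinom(0, size = st$phi, mu = mu, log = TRUE)
  # bivariate normal of (alpha, beta) around the family means
  d1 <- (st$alpha - st$mu_alpha_f) / st$sigma_alpha_f
  d2 <- (st$beta - st$mu_beta_f) / st$sigma_beta_f
  term_fam <- -log(2 * pi) - log(st$sigma_alpha_f * st$sigma_beta_f) -
    0.5 * log(1 - st$omega^2) -
    (d1^2 - 2 * st$omega * d1 * d2 + d2^2) / (2 * (1 - st$omega^2))
  term_means <- dnorm(st$mu_alpha_f, st$mu_alpha, st$sigma_alpha, log = TRUE) +
    dnorm(st$mu_beta_f, st$mu_beta, st$sigma_beta, log = TRUE)
  term_disp <- dlnorm(st$phi, st$a1 * mu + st$a0, st$sigma_phi, log = TRUE)
  term_hyper <- dnorm(st$mu_alpha, 0, 1, log = TRUE) +
    dnorm(st$mu_beta, 0, 1, log = TRUE) +
    dexp(st$sigma_alpha, 1, log = TRUE) + dexp(st$sigma_beta, 1, log = TRUE) +
    dexp(st$sigma_alpha_f, 1, log = TRUE) + dexp(st$sigma_beta_f, 1, log = TRUE) +
    dunif(st$omega, -1, 1, log = TRUE) +
    dnorm(st$a1, 0, 1, log = TRUE) + dnorm(st$a0, 0, 1, log = TRUE) +
    dexp(st$sigma_phi, 1, log = TRUE)
  expect_equal(as.numeric(lp),
               term_lik + term_fam + term_means + term_disp + term_hyper,
               tolerance = 1e-10)
  expect_equal(unname(attr(lp, "terms")["likelihood"]), term_lik,
               tolerance = 1e-10)
})

test_that("duplicating all subjects doubles the likelihood term exactly", {
  sim <- simulate_dataset(6, 9, "over", seed = 2)
  st <- toy_state(6, sim$taxonomy$family_index)
  lp1 <- joint_log_density(st, sim$counts, sim$taxonomy, sim$covariate)
  Y2 <- rbind(sim$counts$counts, sim$counts$counts)
  rownames(Y2) <- paste0("S", seq_len(18))
  cm2 <- count_matrix(Y2, totals = rep(sim$counts$totals, 2))
  x2 <- c(sim$covariate$x, sim$covariate$x)
  lp2 <- joint_log_density(st, cm2, sim$taxonomy, x2)
  t1 <- attr(lp1, "terms")
  t2 <- attr(lp2, "terms")
  expect_equal(unname(t2["likelihood"]), 2 * unname(t1["likelihood"]),
               tolerance = 1e-9)
  # dispersion term changes only through the (identical) average mean
  expect_equal(unname(t2["dispersion"]), unname(t1["dispersion"]),
               tolerance = 1e-9)
})

test_that("disabling the phylogeny reduces to the one-family density", {
  sim <- simulate_dataset(6, 9, "over", seed = 3)
  st <- toy_state(6, sim$taxonomy$family_index)
  st1 <- st
  st1$mu_alpha_f <- st$mu_alpha_f[1]
  st1$mu_beta_f <- st$mu_beta_f[1]
  st1$sigma_alpha_f <- st$sigma_alpha_f[1]
  st1$sigma_beta_f <- st$sigma_beta_f[1]
  one_fam <- family_map(sim$counts$otu_ids, rep("famA", 6))
  lp_nophylo <- joint_log_density(st1, sim$counts, sim$taxonomy,
                                  sim$covariate, use_phylogeny = FALSE)
  lp_onefam <- joint_log_density(st1, sim$counts, one_fam, sim$covariate)
  expect_equal(as.numeric(lp_nophylo), as.numeric(lp_onefam),
               tolerance = 1e-12)
})

test_that("joint log density rejects invalid states", {
  sim <- simulate_dataset(4, 6, "over", seed = 4)
  st <- toy_state(4, sim$taxonomy$family_index)
  bad <- st; bad$omega <- 1.2
  expect_error(joint_log_density(bad, sim$counts, sim$taxonomy,
                                 sim$covariate), "omega")
  bad <- st; bad$phi[2] <- -1
  expect_error(joint_log_density(bad, sim$counts, sim$taxonomy,
                                 sim$covariate), "positive")
  bad <- st; bad$sigma_alpha_f[1] <- 0
  expect_error(joint_log_density(bad, sim$counts, sim$taxonomy,
                                 sim$covariate), "positive")
})

test_that("unconstrained density agrees with the natural-scale density", {
  # lp(unconstrained) = lp(natural) + change-of-variable terms, exactly,
  # for both coefficient parameterizations
  sim <- simulate_dataset(8, 15, "over", seed = 3)
  fi <- sim$taxonomy$family_index
  st <- toy_state(8, fi, seed = 5)
  lpR <- as.numeric(joint_log_density(st, sim$counts, sim$taxonomy,
                                      sim$covariate))
  xbar <- mean(sim$covariate$x)
  jac_pos <- log(st$sigma_alpha) + log(st$sigma_beta) +
    sum(log(st$sigma_alpha_f)) + sum(log(st$sigma_beta_f)) +
    log(st$sigma_phi) + sum(log(st$phi)) + log(1 - st$omega^2)
  thC <- dietbhm:::.bhm_unconstrain(st, fi, centered = TRUE, xbar = xbar)
  lpC <- bhm_lp_grad(thC, sim$counts, sim$taxonomy, sim$covariate,
                     centered = TRUE)$lp
  expect_equal(lpC, lpR + jac_pos, tolerance = 1e-8)
  # non-centered adds the per-OTU log-determinant of the Cholesky factor
  thN <- dietbhm:::.bhm_unconstrain(st, fi, centered = FALSE)
  jac_nc <- sum(log(st$sigma_alpha_f[fi]) + log(st$sigma_beta_f[fi]) +
                  0.5 * log(1 - st$omega^2))
  lpN <- bhm_lp_grad(thN, sim$counts, sim$taxonomy, sim$covariate,
                     centered = FALSE)$lp
  expect_equal(lpN, lpR + jac_pos + jac_nc, tolerance = 1e-8)
})

test_that("analytic gradients match finite differences at random states", {
  sim <- simulate_dataset(6, 12, "over", seed = 9)
  J <- 6; Ff <- 2
  P <- 4 + 4 * Ff + 1 + 2 * J + 3 + J
  for (centered in c(TRUE, FALSE)) {
    set.seed(31)
    for (rep in 1:5) {
      theta <- rnorm(P, 0, 0.5)
      r <- bhm_lp_grad(theta, sim$counts, sim$taxonomy, sim$covariate,
                       centered = centered)
      h <- 1e-5
      fd <- vapply(seq_len(P), function(k) {
        tp <- theta; tm <- theta
        tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
        (bhm_lp_grad(tp, sim$counts, sim$taxonomy, sim$covariate,
                     centered = centered)$lp -
         bhm_lp_grad(tm, sim$counts, sim$taxonomy, sim$covariate,
                     centered = centered)$lp) / (2 * h)
      }, numeric(1))
      rel <- abs(r$grad - fd) / pmax(1e-6, abs(fd) + abs(r$grad))
      expect_lt(max(rel), 1e-4)
    }
  }
})

test_that("model_spec validates and reads YAML configs", {
  expect_error(model_spec(chains = 0), "chains")
  expect_error(model_spec(thin = 0), "thin")
  sp <- model_spec()
  expect_equal(sp$chains, 4L)
  expect_equal(sp$warmup, 1000L)
  expect_equal(sp$draws, 1000L)
  expect_equal(sp$thin, 2L)
  p <- tempfile(fileext = ".yaml")
  writeLines(c("chains: 2", "warmup: 50", "draws: 60", "seed: 9"), p)
  sp2 <- model_spec_from_yaml(p)
  expect_equal(sp2$chains, 2L)
  expect_equal(sp2$draws, 60L)
  writeLines("nonsense: 1", p)
  expect_error(model_spec_from_yaml(p), "unknown config key")
})
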