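test_that("simulated datasets have the stated shape and structure", {
  sim <- simulate_dataset(100, 250, "over", seed = 1)
  expect_equal(dim(sim$counts), c(250L, 100L))
  expect_setequal(unique(sim$taxonomy$family), c("f1", "f2"))
  expect_equal(unname(sim$counts$totals), rep(1, 250)) # unit offset
  expect_equal(nrow(sim$truth), 100)
  expect_true(attr(sim$truth, "mu_x") %in% c(0, 1, -1))
  expect_true(attr(sim$truth, "beta_sign") %in% c(1, -1))
  expect_true(all(is.finite(sim$truth$phi_true)))
  # family means: family 1 slope mean 0, family 2 slope mean +-1
  expect_equal(attr(sim$truth, "mu_beta_family")[1], 0)
  expect_equal(abs(attr(sim$truth, "mu_beta_family")[2]), 1)
})

test_that("skewed datasets square the food scores", {
  sim <- simulate_dataset(10, 50, "over", skew_x = TRUE, seed = 2)
  expect_true(all(sim$covariate$x >= 0))
})

test_that("under-dispersion replaces exactly the top 20% of counts per OTU", {
  sim <- simulate_dataset(12, 37, "under", seed = 3)
  repl <- attr(sim$truth, "replaced")
  expect_equal(unname(colSums(repl)), rep(ceiling(0.2 * 37), 12))
  expect_true(attr(sim$truth, "replace_mode") %in% c("mean", "zero"))
  expect_true(all(is.na(sim$truth$phi_true)))
})

test_that("under-dispersion regimes show the intended count behaviour", {
  # the conditional under-dispersion is visible on the null-slope family,
  # where the covariate does not inflate the marginal variance
  zfrac <- c(); vmr_mean <- c(); n_zero <- 0
  for (s in 1:12) {
    sim <- simulate_dataset(20, 80, "under", seed = 100 + s)
    null_otus <- sim$truth$family == "f1"
    Y <- sim$counts$counts[, null_otus, drop = FALSE]
    if (attr(sim$truth, "replace_mode") == "zero") {
      n_zero <- n_zero + 1
      zfrac <- c(zfrac, colMeans(Y == 0))
    } else {
      vmr_mean <- c(vmr_mean, apply(Y, 2, var) / pmax(colMeans(Y), 1e-9))
    }
  }
  expect_gt(length(vmr_mean), 0)
  expect_gt(n_zero, 0)
  expect_lt(mean(vmr_mean), 1)       # mean-replacement under-disperses
  expect_true(all(zfrac >= 0.2))     # zero-replacement inflates zeros
})

test_that("over-dispersion produces variance beyond Poisson", {
  vmr <- c()
  for (s in 1:6) {
    sim <- simulate_dataset(30, 100, "over", seed = 200 + s)
    Y <- sim$counts$counts
    vmr <- c(vmr, apply(Y, 2, var) / pmax(colMeans(Y), 1e-9))
  }
  expect_gt(mean(vmr > 1), 0.9)
})

test_that("simulated intercepts and slopes carry the -0.7 correlation", {
  sim <- simulate_dataset(4000, 2, "over", seed = 4)
  tr <- sim$truth
  for (f in c("f1", "f2")) {
    r <- cor(tr$alpha_true[tr$family == f], tr$beta_true[tr$family == f])
    expect_lt(abs(r - (-0.7)), 3 / sqrt(sum(tr$family == f)) + 0.02)
  }
  # marginal SDs of 0.1 around the family means
  expect_equal(sd(tr$alpha_true), 0.1, tolerance = 0.02)
})

test_that("over-regime counts track the generative means", {
  sim <- simulate_dataset(50, 400, "over", seed = 5)
  tr <- sim$truth
  x <- sim$covariate$x
  expected <- vapply(seq_len(50), function(j)
    mean(exp(tr$alpha_true[j] + tr$beta_true[j] * x)), numeric(1))
  observed <- colMeans(sim$counts$counts)
  expect_gt(cor(log(observed + 0.5), log(expected)), 0.98)
})

test_that("the full grid manifest has the stated bookkeeping", {
  g <- run_grid(replicates = 100, base_seed = 1)
  expect_equal(nrow(g), 1800)
  expect_equal(length(unique(g$scenario)), 18)
  expect_equal(unname(colSums(table(g$scenario, g$skew_x))["TRUE"] / 18), 50)
  sk <- tapply(g$skew_x, g$scenario, sum)
  expect_true(all(sk == 50))
  g1 <- run_grid(replicates = 1, base_seed = 1)
  expect_equal(nrow(g1), 18)
  expect_identical(run_grid(100, 7), run_grid(100, 7))
  expect_false(identical(run_grid(100, 7)$seed, run_grid(100, 8)$seed))
  expect_true(all(g$seed > 0 & g$seed < .Machine$integer.max))
})

test_that("datasets round-trip through the TSV writer", {
  sim <- simulate_dataset(6, 10, "over", seed = 6)
  dir <- tempfile()
  paths <- write_dataset(sim, dir)
  expect_true(all(file.exists(paths)))
  cm <- read_counts(paths["counts"])
  expect_equal(cm$counts, sim$counts$counts)
  tot <- read.delim(paths["totals"])
  expect_equal(tot$total, unname(sim$counts$totals)) # z = 1 by design
  fm <- read_taxonomy(paths["taxonomy"])
  expect_equal(fm$family, sim$taxonomy$family)
  tr <- read.delim(paths["truth"])
  expect_equal(tr$beta_true, sim$truth$beta_true, tolerance = 1e-9)
})
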