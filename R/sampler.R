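#' Run the built-in No-U-Turn sampler on an arbitrary target
#'
#' Generic interface to the gradient-based MCMC engine used by
#' [fit_bhm()]. The target is supplied as an R function returning the log
#' density and its gradient, which makes the backend pluggable and easy to
#' validate on models with known posteriors.
#'
#' @param lp_grad function of one argument (the parameter vector) returning
#'   `list(lp = <scalar>, grad = <vector>)`.
#' @param init numeric vector of initial values (one chain's start; other
#'   chains are jittered around it).
#' @param chains,warmup,iter,thin,seed,max_treedepth,adapt_delta sampler
#'   controls as in [model_spec()] (`iter` = post-warm-up iterations).
#' @param init_jitter half-width of the per-chain uniform jitter.
#' @param metric_pairs optional two-column integer matrix of (1-based)
#'   coordinate pairs that receive a joint 2x2 block in the adapted
#'   inverse metric instead of independent scalars.
#' @return List with `draws` (array: stored iterations x chains x
#'   parameters), `lp`, and per-chain sampler diagnostics.
#' @export
nuts_sample <- function(lp_grad, init, chains = 4, warmup = 1000,
                        iter = 1000, thin = 1, seed = 1,
                        max_treedepth = 10, adapt_delta = 0.8,
                        init_jitter = 0, metric_pairs = NULL) {
  P <- length(init)
  wrapped <- function(q) {
    res <- lp_grad(q)
    if (!is.list(res) || is.null(res$lp) || is.null(res$grad))
      stop("lp_grad must return list(lp=, grad=)")
    res
  }
  if (is.null(metric_pairs))
    metric_pairs <- matrix(integer(0), 0, 2)
  storage.mode(metric_pairs) <- "integer"
  runner <- function(chain_init) {
    cpp_nuts_rfun(wrapped, chain_init, as.integer(warmup), as.integer(iter),
                  as.integer(thin), as.integer(max_treedepth), adapt_delta,
                  metric_pairs)
  }
  .run_chains(runner, init, chains, warmup, iter, thin, seed, init_jitter, P)
}

# Shared chain loop: derives per-chain seeds from `seed`, jitters the
# initial values, runs each chain and assembles the draws array.
.run_chains <- function(runner, init, chains, warmup, iter, thin, seed,
                        init_jitter, P) {
  set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  n_store <- iter %/% thin
  draws <- array(NA_real_, c(n_store, chains, P))
  lp <- matrix(NA_real_, n_store, chains)
  diag_list <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    chain_init <- init +
      if (init_jitter > 0) stats::runif(P, -init_jitter, init_jitter) else 0
    res <- runner(chain_init)
    draws[, ch, ] <- res$draws
    lp[, ch] <- res$lp
    diag_list[[ch]] <- list(
      accept_stat = res$accept_stat, treedepth = res$treedepth,
      n_leapfrog = res$n_leapfrog, divergent = res$divergent,
      energy = res$energy, n_divergent = res$n_divergent,
      warmup_n_leapfrog = res$warmup_n_leapfrog,
      stepsize = res$stepsize, n_evals = res$n_evals)
  }
  list(draws = draws, lp = lp, chains = diag_list,
       chain_seeds = chain_seeds)
}

#' Split R-hat and effective sample size
#'
#' Split-chain potential scale reduction and effective sample size
#' (Geyer initial-monotone estimator on split chains), computed per
#' parameter of a draws array.
#'
#' @param draws array of dimension iterations x chains x parameters (a
#'   matrix is treated as one parameter per column with a single chain).
#' @return Data frame with one row per parameter: `rhat` and `ess`.
#' @export
mcmc_diagnostics <- function(draws) {
  if (is.matrix(draws)) draws <- array(draws, c(nrow(draws), 1, ncol(draws)))
  S <- dim(draws)[1]; C <- dim(draws)[2]; K <- dim(draws)[3]
  n <- S %/% 2
  if (n < 2) stop("need at least 4 iterations for split diagnostics")
  m <- 2L * C
  # n x (m*K) matrix of split chains, split-chain index fastest
  X <- matrix(NA_real_, n, m * K)
  for (k in seq_len(K)) {
    for (ch in seq_len(C)) {
      X[, (k - 1) * m + 2 * ch - 1] <- draws[seq_len(n), ch, k]
      X[, (k - 1) * m + 2 * ch] <- draws[n + seq_len(n), ch, k]
    }
  }
  mu <- colMeans(X)
  v <- apply(X, 2, var)
  rhat <- numeric(K); ess <- numeric(K)
  ac <- .fft_autocov(X) # lag x columns, biased autocovariance
  max_lag <- nrow(ac) - 1
  for (k in seq_len(K)) {
    cols <- (k - 1) * m + seq_len(m)
    W <- mean(v[cols])
    B <- n * var(mu[cols])
    var_plus <- W * (n - 1) / n + B / n
    rhat[k] <- if (W > 1e-300) sqrt(var_plus / W) else NA_real_
    if (!is.finite(rhat[k]) || W <= 1e-300) {
      ess[k] <- NA_real_
      next
    }
    # mean autocovariance across split chains
    acov <- rowMeans(ac[, cols, drop = FALSE])
    rho <- 1 - (W - acov) / var_plus
    # Geyer initial positive/monotone sequence on paired sums
    npair <- (max_lag + 1) %/% 2
    tau <- -rho[1] # corrects for lag-0 counted twice below
    prev <- Inf
    for (p in seq_len(npair)) {
      s <- rho[2 * p - 1] + if (2 * p <= max_lag + 1) rho[2 * p] else 0
      if (!is.finite(s) || s <= 0) break
      s <- min(s, prev)
      prev <- s
      tau <- tau + 2 * s
    }
    tau <- max(tau, 1 / (m * n)) # guard
    ess[k] <- m * n / max(tau, 1e-12)
  }
  data.frame(rhat = rhat, ess = ess)
}

# biased autocovariances (lags 0..min(n-1, 400)) for all columns via FFT
.fft_autocov <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  L <- 2^ceiling(log2(2 * n))
  pad <- rbind(Xc, matrix(0, L - n, ncol(X)))
  f <- stats::mvfft(pad)
  ac <- Re(stats::mvfft(f * Conj(f), inverse = TRUE)) / L
  lag_max <- min(n - 1, 400)
  ac[seq_len(lag_max + 1), , drop = FALSE] / n
}
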