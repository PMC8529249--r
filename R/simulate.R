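#' Simulate one diet-microbiome dataset with ground truth
#'
#' Generates a synthetic dataset from the two-family generative process
#' used in the simulation study:
#' \enumerate{
#'   \item each OTU is assigned uniformly at random to one of two families
#'     (assignment is redrawn if a family ends up empty); family 1 has
#'     intercept/slope means (2, 0), family 2 has (2, +1) or (2, -1) with
#'     the sign drawn per dataset, all with SD 0.1;
#'   \item food-item scores are drawn as Normal(mu_x, 1) with mu_x drawn
#'     uniformly from \{0, +1, -1\}; with `skew_x` the scores are squared
#'     to produce a skewed distribution;
#'   \item per-OTU intercepts and slopes come from a bivariate normal with
#'     the family means, SDs 0.1 and correlation -0.7;
#'   \item counts: in the over-dispersion regime, negative binomial with
#'     log mean `alpha + beta * x` and dispersion drawn from a lognormal
#'     with location `0.1 / alpha` and scale 0.1; in the under-dispersion
#'     regime, Poisson counts whose top 20% per OTU are replaced either by
#'     the (rounded) average OTU count or by zero, the replacement mode
#'     drawn per dataset.
#' }
#' Total counts are fixed at `z = 1` (zero log offset) so that parameter
#' recovery is well defined.
#'
#' @param n_otu number of OTUs (the study grid uses 10, 100 or 200).
#' @param n_subj number of subjects (the grid uses 50, 250 or 500).
#' @param dispersion `"over"` or `"under"`.
#' @param skew_x square the food-item scores.
#' @param seed integer seed.
#' @param beta_sign optionally force the sign of family 2's slope mean
#'   (`+1` or `-1`); default drawn at random.
#' @return List with elements `counts` ([count_matrix]), `taxonomy`
#'   ([family_map]), `covariate` ([covariate_vector]) and `truth`, a data
#'   frame (otu_id, family, alpha_true, beta_true, phi_true) with
#'   attributes `mu_x`, `beta_sign`, `mu_beta_family` (the two family-level
#'   slope means), `replace_mode` and `replaced` (bookkeeping of which
#'   counts were replaced in the under-dispersion regime).
#' @export
simulate_dataset <- function(n_otu, n_subj, dispersion = c("over", "under"),
                             skew_x = FALSE, seed = 1, beta_sign = NULL) {
  dispersion <- match.arg(dispersion)
  stopifnot(n_otu >= 2, n_subj >= 2)
  set.seed(as.integer(seed))
  fam <- sample(1:2, n_otu, replace = TRUE)
  while (length(unique(fam)) < 2) fam <- sample(1:2, n_otu, replace = TRUE)
  if (is.null(beta_sign)) beta_sign <- sample(c(1, -1), 1)
  stopifnot(beta_sign %in% c(1, -1))
  mu_beta_fam <- c(0, beta_sign * 1)
  mu_alpha_fam <- c(2, 2)
  sd_ab <- 0.1
  rho <- -0.7
  mu_x <- sample(c(0, 1, -1), 1)
  x <- rnorm(n_subj, mu_x, 1)
  if (skew_x) x <- x^2
  # bivariate normal draws via the Cholesky factor
  z1 <- rnorm(n_otu)
  z2 <- rnorm(n_otu)
  alpha <- mu_alpha_fam[fam] + sd_ab * z1
  beta <- mu_beta_fam[fam] + sd_ab * (rho * z1 + sqrt(1 - rho^2) * z2)
  eta <- outer(x, beta) + rep(alpha, each = n_subj)
  mu <- exp(eta)
  replaced <- NULL
  replace_mode <- NA_character_
  if (dispersion == "over") {
    phi <- rlnorm(n_otu, meanlog = 0.1 / alpha, sdlog = 0.1)
    Y <- matrix(rnbinom(n_subj * n_otu, size = rep(phi, each = n_subj),
                        mu = mu), n_subj, n_otu)
  } else {
    phi <- rep(NA_real_, n_otu)
    Y <- matrix(rpois(n_subj * n_otu, mu), n_subj, n_otu)
    replace_mode <- sample(c("mean", "zero"), 1)
    k <- ceiling(0.2 * n_subj)
    replaced <- matrix(FALSE, n_subj, n_otu)
    for (j in seq_len(n_otu)) {
      top <- order(Y[, j], decreasing = TRUE)[seq_len(k)]
      val <- if (replace_mode == "mean") round(mean(Y[, j])) else 0L
      Y[top, j] <- val
      replaced[top, j] <- TRUE
    }
  }
  otu_ids <- sprintf("OTU%03d", seq_len(n_otu))
  subject_ids <- sprintf("S%03d", seq_len(n_subj))
  dimnames(Y) <- list(subject_ids, otu_ids)
  truth <- data.frame(otu_id = otu_ids, family = paste0("f", fam),
                      alpha_true = alpha, beta_true = beta, phi_true = phi,
                      stringsAsFactors = FALSE)
  attr(truth, "mu_x") <- mu_x
  attr(truth, "beta_sign") <- beta_sign
  attr(truth, "mu_beta_family") <- mu_beta_fam
  attr(truth, "replace_mode") <- replace_mode
  attr(truth, "replaced") <- replaced
  list(counts = count_matrix(Y, totals = rep(1, n_subj)),
       taxonomy = family_map(otu_ids, paste0("f", fam)),
       covariate = covariate_vector(x, subject_ids, name = "food_item"),
       truth = truth)
}

#' Manifest of the full simulation grid
#'
#' The study grid crosses 3 OTU counts (10, 100, 200), 3 subject counts
#' (50, 250, 500) and 2 dispersion regimes into 18 scenarios; with 100
#' replicates per scenario this yields 1,800 datasets, 50 of which per
#' scenario have squared (skewed) food-item scores.
#'
#' @param replicates datasets per scenario.
#' @param base_seed seed from which all per-dataset seeds are derived.
#' @return Data frame with one row per dataset: `scenario`, `n_otu`,
#'   `n_subj`, `dispersion`, `replicate`, `skew_x`, `seed`. Pass a row's
#'   settings to [simulate_dataset()] to materialize it.
#' @export
run_grid <- function(replicates = 100, base_seed = 1) {
  stopifnot(replicates >= 1)
  grid <- expand.grid(n_otu = c(10, 100, 200),
                      n_subj = c(50, 250, 500),
                      dispersion = c("over", "under"),
                      stringsAsFactors = FALSE)
  grid$scenario <- seq_len(nrow(grid))
  set.seed(as.integer(base_seed))
  seeds <- sample.int(.Machine$integer.max - 1L,
                      nrow(grid) * replicates)
  out <- grid[rep(seq_len(nrow(grid)), each = replicates), ]
  out$replicate <- rep(seq_len(replicates), times = nrow(grid))
  # half of the replicates per scenario get skewed scores
  out$skew_x <- out$replicate <= floor(replicates / 2)
  out$seed <- seeds
  rownames(out) <- NULL
  out[, c("scenario", "n_otu", "n_subj", "dispersion", "replicate",
          "skew_x", "seed")]
}

#' Write one simulated dataset to TSV files
#'
#' Writes the count, taxonomy, covariate and ground-truth tables of a
#' simulated dataset, plus a one-line JSON manifest.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, paste0(prefix, "_counts.tsv")),
             taxonomy = file.path(dir, paste0(prefix, "_taxonomy.tsv")),
             covariate = file.path(dir, paste0(prefix, "_covariate.tsv")),
             totals = file.path(dir, paste0(prefix, "_totals.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")),
             manifest = file.path(dir, paste0(prefix, "_manifest.json")))
  write_counts(sim$counts, paths["counts"])
  write.table(sim$taxonomy[, c("otu_id", "family")], paths["taxonomy"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(subject_id = sim$covariate$subject_ids,
                         food_item = sim$covariate$x),
              paths["covariate"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  # the design fixes the offset at z = 1, which row sums cannot recover
  write.table(data.frame(subject_id = sim$counts$subject_ids,
                         total = sim$counts$totals),
              paths["totals"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- list(n_otu = length(sim$counts$otu_ids),
                   n_subj = length(sim$counts$subject_ids),
                   mu_x = attr(sim$truth, "mu_x"),
                   beta_sign = attr(sim$truth, "beta_sign"),
                   replace_mode = attr(sim$truth, "replace_mode"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
             paths["manifest"])
  invisible(paths)
}
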