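# small fixture builders shared across test files

toy_counts_file <- function(tab, ids = paste0("S", seq_len(nrow(tab))),
                            otus = paste0("OTU", seq_len(ncol(tab)))) {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(subject_id = ids, tab, check.names = FALSE)
  colnames(df) <- c("subject_id", otus)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_taxonomy_file <- function(otus, field, column = "family") {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(otu_id = otus, x = field)
  colnames(df) <- c("otu_id", column)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a small valid natural-scale parameter state for a 2-family model
toy_state <- function(J, fam_index, seed = 42) {
  set.seed(seed)
  list(mu_alpha = 0.3, mu_beta = -0.2, sigma_alpha = 0.8, sigma_beta = 1.2,
       mu_alpha_f = c(1.8, 2.1), mu_beta_f = c(0.1, -0.9),
       sigma_alpha_f = c(0.15, 0.2), sigma_beta_f = c(0.1, 0.25),
       omega = -0.5,
       alpha = rnorm(J, 2, 0.2), beta = rnorm(J, 0, 0.2),
       phi = exp(rnorm(J, 0, 0.2)),
       a1 = 0.05, a0 = -0.2, sigma_phi = 0.7)
}

# quick sampler settings for unit tests
tiny_spec <- function(...) {
  model_spec(chains = 2, warmup = 150, draws = 150, ...)
}
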