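#' Mean squared error of slope estimates
#'
#' @param est estimated slopes.
#' @param truth true slopes (same length; OTUs excluded from estimation
#'   must be removed from both beforehand).
#' @return Mean of squared differences.
#' @export
mse <- function(est, truth) {
  if (length(est) != length(truth)) stop("length mismatch")
  mean((est - truth)^2)
}

#' Bias of slope estimates (estimated minus true)
#'
#' @inheritParams mse
#' @return Mean of `est - truth`.
#' @export
bias <- function(est, truth) {
  if (length(est) != length(truth)) stop("length mismatch")
  mean(est - truth)
}

#' Coverage of 95% interval estimates
#'
#' Fraction of OTUs whose true slope lies inside the interval (closed at
#' both ends).
#'
#' @param lower,upper interval bounds per OTU.
#' @inheritParams mse
#' @return Coverage in `[0, 1]`.
#' @export
coverage95 <- function(lower, upper, truth) {
  if (length(lower) != length(truth) || length(upper) != length(truth))
    stop("length mismatch")
  if (any(lower > upper)) stop("inverted interval(s)")
  mean(lower <= truth & truth <= upper)
}

#' False discovery rate of significance calls
#'
#' Standard definition: the number of significant OTUs whose true slope is
#' null, divided by the number of significant OTUs (0 when nothing is
#' declared significant). "Truly null" is membership in the zero-mean
#' slope family of the generative model; the per-OTU realized slopes are
#' jittered around 0, so a strict-zero definition would be empty.
#'
#' @param significant logical vector of significance calls per OTU.
#' @param truly_null logical vector: `TRUE` for OTUs whose true (family
#'   mean) slope is zero.
#' @return FDR in `[0, 1]`, with attribute `"literal_ratio"` giving the
#'   ratio of truly-null OTUs to false positives (a debugging quantity;
#'   `NA` when there are no false positives).
#' @export
fdr <- function(significant, truly_null) {
  if (length(significant) != length(truly_null)) stop("length mismatch")
  n_sig <- sum(significant)
  n_false <- sum(significant & truly_null)
  out <- n_false / max(1, n_sig)
  attr(out, "literal_ratio") <-
    if (n_false > 0) sum(truly_null) / n_false else NA_real_
  out
}

#' Evaluate one method's slope estimates against the simulation truth
#'
#' Computes all four performance measures (MSE, bias, 95% interval
#' coverage, FDR) of a set of per-OTU slope estimates against the attached
#' ground truth, excluding flagged OTUs.
#'
#' @param est,lower,upper,significant per-OTU estimates, interval bounds
#'   and significance calls.
#' @param truth the `truth` data frame of [simulate_dataset()].
#' @param keep logical vector of OTUs to evaluate (e.g. the convergence
#'   flag of [fit_nb_glm()]); defaults to all with finite estimates.
#' @param method label for the output row.
#' @return One-row data frame: `method`, `mse`, `bias`, `coverage`, `fdr`,
#'   `fdr_literal`, `n_eval`, `n_excluded`.
#' @export
evaluate_slopes <- function(est, lower, upper, significant, truth,
                            keep = NULL, method = "method") {
  stopifnot(nrow(truth) == length(est))
  if (is.null(keep)) keep <- is.finite(est) & is.finite(lower) & is.finite(upper)
  keep <- keep & is.finite(est)
  tb <- truth$beta_true[keep]
  null_fam <- truth$family[keep] == "f1"
  f <- fdr(significant[keep], null_fam)
  data.frame(method = method,
             mse = mse(est[keep], tb),
             bias = bias(est[keep], tb),
             coverage = coverage95(lower[keep], upper[keep], tb),
             fdr = as.numeric(f),
             fdr_literal = attr(f, "literal_ratio"),
             n_eval = sum(keep), n_excluded = sum(!keep),
             stringsAsFactors = FALSE)
}

#' Stack evaluation rows into a long-format report
#'
#' Pivots one or more [evaluate_slopes()] rows (optionally carrying
#' scenario columns such as `n_otu`, `n_subj`, `dispersion`) into a long
#' table with one row per (scenario, method, metric).
#'
#' @param ev data frame of evaluation rows.
#' @param path optional TSV output path.
#' @return Long-format data frame with columns of `ev` other than the
#'   metrics, plus `metric` and `value`.
#' @export
eval_report_long <- function(ev, path = NULL) {
  metrics <- intersect(c("mse", "bias", "coverage", "fdr", "fdr_literal"),
                       names(ev))
  id_cols <- setdiff(names(ev), metrics)
  out <- do.call(rbind, lapply(metrics, function(m) {
    cbind(ev[, id_cols, drop = FALSE],
          data.frame(metric = m, value = ev[[m]],
                     stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
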