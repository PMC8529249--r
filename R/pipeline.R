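#' Prevalence and family-size filtering of OTUs
#'
#' Applies the two selection rules of the cohort workflow, in order:
#' first keep OTUs with a positive count in at least `prevalence` of the
#' subjects, then keep OTUs belonging to an identified (non-"unclassified")
#' phylogenetic family that still has at least `min_family_size` members.
#'
#' @param counts a [count_matrix].
#' @param fam a [family_map].
#' @param prevalence minimum fraction of subjects with a positive count
#'   (default 0.2).
#' @param min_family_size minimum family size after the prevalence filter
#'   (default 5, i.e. each OTU shares its family with at least four
#'   others).
#' @param totals `"original"` keeps the pre-filter per-subject totals as
#'   the offset (they represent sequencing depth); `"recompute"` re-derives
#'   them from the retained OTUs.
#' @return List with the filtered `counts` and `taxonomy`.
#' @export
filter_otus <- function(counts, fam, prevalence = 0.2, min_family_size = 5,
                        totals = c("original", "recompute")) {
  totals <- match.arg(totals)
  stopifnot(inherits(counts, "count_matrix"), prevalence > 0,
            prevalence <= 1, min_family_size >= 1)
  if (!inherits(fam, "family_map")) fam <- family_map(names(fam), fam)
  idx <- match(counts$otu_ids, fam$otu_id)
  if (anyNA(idx)) stop("OTU(s) missing from the family map")
  families <- fam$family[idx]
  n_subj <- nrow(counts$counts)
  prev_ok <- colSums(counts$counts > 0) >= prevalence * n_subj
  keep <- prev_ok
  fam_sizes <- table(families[keep])
  fam_ok <- families != "unclassified" &
    families %in% names(fam_sizes)[fam_sizes >= min_family_size]
  keep <- keep & fam_ok
  if (!any(keep)) stop("no OTUs retained after filtering")
  Y <- counts$counts[, keep, drop = FALSE]
  new_tot <- if (totals == "original") counts$totals else rowSums(Y)
  if (any(new_tot <= 0))
    stop("subject(s) with zero total count after filtering; remove them first")
  list(counts = count_matrix(Y, totals = new_tot),
       taxonomy = family_map(counts$otu_ids[keep], families[keep]))
}

#' Split the OTU set into analysis batches by family abundance
#'
#' Families are ordered by decreasing average relative abundance (mean over
#' subjects of the family's summed relative abundance) and packed greedily
#' into batches of at most `max_otus_per_batch` OTUs. A family is never
#' split across batches unless it alone exceeds the cap, in which case it
#' is split into cap-sized chunks.
#'
#' @inheritParams filter_otus
#' @param max_otus_per_batch batch capacity (default 200).
#' @return An object of class `batch_plan`: list with `batches` (list of
#'   OTU-id vectors), `family_order`, `family_batch` (data frame recording
#'   which batch(es) each family went to) and `max_otus_per_batch`.
#' @export
make_batches <- function(counts, fam, max_otus_per_batch = 200) {
  stopifnot(inherits(counts, "count_matrix"), max_otus_per_batch >= 1)
  if (!inherits(fam, "family_map")) fam <- family_map(names(fam), fam)
  idx <- match(counts$otu_ids, fam$otu_id)
  if (anyNA(idx)) stop("OTU(s) missing from the family map")
  families <- fam$family[idx]
  rel <- counts$counts / counts$totals
  fam_levels <- unique(families)
  fam_abund <- vapply(fam_levels, function(f)
    mean(rowSums(rel[, families == f, drop = FALSE])), numeric(1))
  ord <- fam_levels[order(-fam_abund)]
  batches <- list()
  current <- character(0)
  rec <- list()
  for (f in ord) {
    otus <- counts$otu_ids[families == f]
    if (length(otus) <= max_otus_per_batch - length(current)) {
      current <- c(current, otus)
      rec[[f]] <- length(batches) + 1L
    } else if (length(otus) <= max_otus_per_batch) {
      batches[[length(batches) + 1L]] <- current
      current <- otus
      rec[[f]] <- length(batches) + 1L
    } else {
      # oversized family: close the open batch, emit cap-sized chunks
      if (length(current) > 0) batches[[length(batches) + 1L]] <- current
      chunks <- split(otus, ceiling(seq_along(otus) / max_otus_per_batch))
      ids <- integer(0)
      for (chunk in chunks) {
        if (length(chunk) == max_otus_per_batch) {
          batches[[length(batches) + 1L]] <- chunk
          ids <- c(ids, length(batches))
        } else {
          current <- chunk # remainder opens the next batch
          ids <- c(ids, length(batches) + 1L)
        }
      }
      if (length(chunks[[length(chunks)]]) == max_otus_per_batch)
        current <- character(0)
      rec[[f]] <- ids
    }
  }
  if (length(current) > 0) batches[[length(batches) + 1L]] <- current
  family_batch <- data.frame(
    family = rep(names(rec), lengths(rec)),
    batch = unlist(rec, use.names = FALSE),
    stringsAsFactors = FALSE)
  structure(list(batches = batches, family_order = ord,
                 family_batch = family_batch,
                 max_otus_per_batch = max_otus_per_batch),
            class = "batch_plan")
}

#' @export
print.batch_plan <- function(x, ...) {
  cat(sprintf("batch_plan: %d batch(es), cap %d OTUs\n",
              length(x$batches), x$max_otus_per_batch))
  for (b in seq_along(x$batches))
    cat(sprintf("  batch %d: %d OTUs\n", b, length(x$batches[[b]])))
  invisible(x)
}

#' Fit one food item across all batches
#'
#' Runs the hierarchical model batch by batch with the shared offset and
#' concatenates the per-OTU association summaries, Bonferroni-corrected
#' over the number of batches. Within a batch no further correction is
#' applied (the hierarchical model already shrinks the estimates).
#'
#' @inheritParams fit_bhm
#' @param plan a [make_batches()] plan covering the OTUs of `counts`.
#' @return Association table as in [summarize_associations()], plus
#'   `batch`, `batch_max_rhat` and `batch_converged` columns.
#' @export
run_food_item <- function(counts, fam, x, plan, spec = model_spec(),
                          food_item = NULL) {
  stopifnot(inherits(plan, "batch_plan"))
  all_b <- unlist(plan$batches)
  if (!setequal(all_b, counts$otu_ids) || anyDuplicated(all_b))
    stop("batch plan does not partition the OTUs of the count matrix")
  n_batches <- length(plan$batches)
  out <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    otus <- plan$batches[[b]]
    sub <- count_matrix(counts$counts[, otus, drop = FALSE],
                        totals = counts$totals)
    fit <- fit_bhm(sub, fam, x, spec = spec, food_item = food_item)
    tab <- summarize_associations(fit, n_batches = n_batches)
    tab$batch <- b
    tab$batch_max_rhat <- fit$max_rhat
    tab$batch_converged <- fit$converged
    out[[b]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
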