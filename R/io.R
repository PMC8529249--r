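#' Construct a validated OTU count matrix
#'
#' Container for a subjects-by-OTUs table of sequencing read counts together
#' with per-subject total counts (library sizes) used as the model offset.
#'
#' @param counts integer matrix, subjects in rows, OTUs in columns; row and
#'   column names are used as subject/OTU identifiers when present.
#' @param subject_ids,otu_ids optional identifier vectors overriding the
#'   dimnames of `counts`.
#' @param totals per-subject total counts. Defaults to the row sums of
#'   `counts`; pass explicitly when the library size was determined before
#'   filtering (or, for simulated data, fixed by design).
#' @return An object of class `count_matrix` with elements `counts`,
#'   `subject_ids`, `otu_ids` and `totals`.
#' @export
count_matrix <- function(counts, subject_ids = rownames(counts),
                         otu_ids = colnames(counts), totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(ncol(counts)))
  subject_ids <- as.character(subject_ids)
  otu_ids <- as.character(otu_ids)
  if (length(subject_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stop("identifier lengths do not match the count matrix")
  if (anyDuplicated(subject_ids))
    stop("duplicate subject identifiers: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU identifiers: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  .check_count_entries(counts, subject_ids, otu_ids)
  # counts stay numeric: integer-valued, but deep-sequencing or simulated
  # libraries can exceed the 32-bit integer range
  storage.mode(counts) <- "double"
  auto <- is.null(totals)
  if (auto) totals <- rowSums(counts)
  totals <- as.numeric(totals)
  if (length(totals) != nrow(counts))
    stop("totals must have one entry per subject")
  if (any(totals <= 0))
    stop("non-positive total count for subject(s): ",
         paste(subject_ids[totals <= 0], collapse = ", "))
  dimnames(counts) <- list(subject_ids, otu_ids)
  structure(list(counts = counts, subject_ids = subject_ids,
                 otu_ids = otu_ids, totals = totals,
                 totals_auto = auto),
            class = "count_matrix")
}

.check_count_entries <- function(m, subject_ids, otu_ids) {
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "count for subject '%s', OTU '%s' is '%s'; counts must be non-negative integers",
      subject_ids[i], otu_ids[j], format(m[i, j])))
  }
  invisible(TRUE)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d subjects x %d OTUs; total counts %s..%s\n",
              nrow(x$counts), ncol(x$counts),
              format(min(x$totals)), format(max(x$totals))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read an OTU count table from a TSV file
#'
#' The file must have a header row and a first column of identifiers; the
#' body must consist of non-negative integers. Both orientations are
#' supported via `orientation`; the default follows the convention of one
#' row per subject.
#'
#' @param path path to a tab-separated file.
#' @param orientation `"subjects_rows"` (default) or `"otus_rows"`.
#' @param totals optional per-subject totals; defaults to row sums.
#' @return A [count_matrix].
#' @export
read_counts <- function(path, orientation = c("subjects_rows", "otus_rows"),
                        totals = NULL) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, function(col) as.numeric(as.character(col)),
           numeric(nrow(body))))
  if (nrow(body) == 1) num <- matrix(num, nrow = 1)
  nonnum <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(nonnum) > 0)
    stop(sprintf("non-numeric count '%s' at row '%s', column '%s'",
                 as.matrix(body)[nonnum[1, , drop = FALSE]],
                 ids[nonnum[1, 1]], colnames(body)[nonnum[1, 2]]))
  rownames(num) <- ids
  if (orientation == "otus_rows") num <- t(num)
  count_matrix(num, totals = totals)
}

#' Write an OTU count table to a TSV file
#'
#' @param x a [count_matrix].
#' @param path output path.
#' @param id_column name for the identifier column (default `"subject_id"`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, id_column = "subject_id") {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(x$subject_ids, x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, x$otu_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an OTU-to-family map
#'
#' Maps each OTU to the phylogenetic family used as its shrinkage group.
#' OTUs without an identified family carry the reserved label
#' `"unclassified"`.
#'
#' @param otu_ids character vector of OTU identifiers.
#' @param families character vector of family labels, one per OTU.
#' @return An object of class `family_map`: a data frame with columns
#'   `otu_id`, `family` and integer `family_index`.
#' @export
family_map <- function(otu_ids, families) {
  otu_ids <- as.character(otu_ids)
  families <- as.character(families)
  if (length(otu_ids) != length(families))
    stop("otu_ids and families must have the same length")
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU identifiers in family map")
  if (any(is.na(families) | families == ""))
    families[is.na(families) | families == ""] <- "unclassified"
  fac <- factor(families, levels = unique(families))
  out <- data.frame(otu_id = otu_ids, family = families,
                    family_index = as.integer(fac),
                    stringsAsFactors = FALSE)
  attr(out, "family_levels") <- levels(fac)
  class(out) <- c("family_map", "data.frame")
  out
}

#' Extract the family label from a Greengenes-style lineage string
#'
#' @param lineage character vector of lineage strings, e.g.
#'   `"k__Bacteria;...;f__Lachnospiraceae;g__Blautia"`.
#' @return Character vector of family names; an empty `f__` token (or a
#'   missing one when `strict = FALSE`) yields `"unclassified"`.
#' @param strict error when no `f__` token is present (default `TRUE`).
#' @export
parse_family <- function(lineage, strict = TRUE) {
  m <- regmatches(lineage, regexpr("f__[^;]*", lineage))
  has <- grepl("f__", lineage)
  if (strict && !all(has))
    stop("no f__ token in lineage: ", lineage[!has][1])
  out <- rep("unclassified", length(lineage))
  val <- sub("^f__", "", m)
  val <- trimws(val)
  out[has] <- ifelse(val == "", "unclassified", val)
  out
}

#' Read an OTU taxonomy table from a TSV file
#'
#' Accepts either a two-column file (`otu_id`, `family`) or a file with a
#' lineage/taxonomy column containing Greengenes-style `f__` tokens.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A [family_map].
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("taxonomy file must have an otu id column and a family or lineage column")
  ids <- as.character(df[[1]])
  nms <- tolower(colnames(df))
  if ("family" %in% nms) {
    fams <- as.character(df[[which(nms == "family")[1]]])
    fams[is.na(fams) | fams == ""] <- "unclassified"
  } else {
    cand <- which(vapply(df, function(col) any(grepl("f__", col)), logical(1)))
    if (length(cand) == 0)
      stop("no 'family' column and no lineage column with an f__ token")
    fams <- parse_family(as.character(df[[cand[1]]]), strict = TRUE)
  }
  family_map(ids, fams)
}

#' Construct a food-item covariate vector
#'
#' @param x numeric food-item scores, one per subject.
#' @param subject_ids subject identifiers (defaults to names of `x`).
#' @param name name of the food item.
#' @param standardized whether `x` is already standardized.
#' @return An object of class `covariate_vector`.
#' @export
covariate_vector <- function(x, subject_ids = names(x), name = "food_item",
                             standardized = FALSE) {
  x <- as.numeric(x)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_along(x))
  if (length(subject_ids) != length(x))
    stop("subject_ids must match the length of x")
  if (anyDuplicated(subject_ids)) stop("duplicate subject identifiers")
  if (any(!is.finite(x))) stop("non-finite covariate value")
  if (standardized &&
      (abs(mean(x)) > 1e-8 || abs(sd(x) - 1) > 1e-8))
    stop("covariate marked standardized but mean/sd are not 0/1")
  structure(list(x = x, subject_ids = as.character(subject_ids),
                 name = name, standardized = standardized),
            class = "covariate_vector")
}

#' Read per-subject food-item scores from a TSV file
#'
#' @param path path to a tab-separated file: first column subject ids,
#'   remaining numeric columns one food item each.
#' @param item food item (column) to extract; defaults to the first.
#' @return A [covariate_vector].
#' @export
read_covariates <- function(path, item = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("covariate file must have subject ids plus scores")
  ids <- as.character(df[[1]])
  if (is.null(item)) item <- colnames(df)[2]
  if (!item %in% colnames(df)) stop("no column named '", item, "'")
  covariate_vector(as.numeric(df[[item]]), ids, name = item)
}

#' Standardize a covariate to mean zero and unit sample variance
#'
#' Uses the sample standard deviation (denominator n-1). Idempotent up to
#' numerical tolerance.
#'
#' @param cv a [covariate_vector] (or plain numeric vector).
#' @return The standardized covariate with the `standardized` flag set.
#' @export
standardize <- function(cv) {
  plain <- !inherits(cv, "covariate_vector")
  x <- if (plain) as.numeric(cv) else cv$x
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant covariate (zero variance)")
  z <- (x - mean(x)) / s
  if (plain) return(z)
  covariate_vector(z, cv$subject_ids, cv$name, standardized = TRUE)
}
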