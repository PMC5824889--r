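## Taxon-resolved distribution analysis: genus-balanced subsampling,
## collapsing occurrence matrices to taxon level, genus-specificity scoring
## and rank-level overlap counts.

#' Genus-balanced subsampling of data sets
#'
#' Genera with fewer than `min_n` data sets are excluded; genera with at
#' most `cap` are fully included; genera with more than `cap` contribute
#' `cap` uniformly random data sets (without replacement, seeded).
#'
#' @param datasets A tibble with columns `dataset_id` and `genus` (e.g. from
#'   [dataset_registry()]).
#' @param cap Maximum data sets per genus (default 50).
#' @param min_n Minimum genus availability for inclusion (default 20).
#' @param seed Optional integer seed for the random draws.
#' @return Character vector of selected `dataset_id`s.
#' @export
subsample_datasets <- function(datasets, cap = 50L, min_n = 20L,
                               seed = NULL) {
  datasets <- tibble::as_tibble(datasets)
  stopifnot(all(c("dataset_id", "genus") %in% names(datasets)))
  draw <- function() {
    unlist(lapply(split(datasets$dataset_id, datasets$genus), function(ids) {
      if (length(ids) < min_n) return(character(0))
      if (length(ids) <= cap) return(ids)
      sample(ids, cap)
    }), use.names = FALSE)
  }
  sel <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  sel[order(match(sel, datasets$dataset_id))]
}

map_columns_to_taxa <- function(dataset_ids, registry, rank) {
  rank <- match.arg(rank, c("species", "genus", "family", "suborder"))
  i <- match(dataset_ids, registry$dataset_id)
  if (anyNA(i)) {
    stop("columns without taxonomy: ",
         paste(utils::head(dataset_ids[is.na(i)], 5), collapse = ", "),
         call. = FALSE)
  }
  registry[[rank]][i]
}

#' Collapse an occurrence matrix to taxon level
#'
#' Combines all data-set columns belonging to one taxon of the requested
#' rank and counts the occurrences: entry (row, taxon) is the number of the
#' taxon's data sets in which the row is present. Input values are
#' binarised first (presence = value > 0).
#'
#' @param mat An [occurrence_matrix()] with data-set columns.
#' @param registry A dataset registry (see [dataset_registry()]) mapping
#'   `dataset_id` to taxonomy.
#' @param rank One of `"species"`, `"genus"`, `"family"`, `"suborder"`.
#' @return A count [occurrence_matrix()] with taxon columns; the number of
#'   data sets per taxon is stored in the `"n_datasets"` attribute.
#' @export
collapse_matrix <- function(mat, registry, rank) {
  taxa <- map_columns_to_taxa(colnames(mat), registry, rank)
  pres <- (unclass(mat) > 0) * 1
  out <- t(rowsum(t(pres), group = taxa))
  n_ds <- as.integer(table(taxa)[colnames(out)])
  res <- occurrence_matrix(out, values = "count", rank = rank)
  attr(res, "n_datasets") <- stats::setNames(n_ds, colnames(out))
  res
}

#' Score genus specificity of rows
#'
#' For each row of a genus-collapsed count matrix, the relative occurrence
#' is the fraction of the row's total detections that fall in its top genus.
#' Classes use strict thresholds: `unique` iff the fraction equals 1,
#' `highly_specific` iff it exceeds 0.95 (but is below 1), else
#' `nonspecific`; 0.95 exactly is nonspecific. Rows with zero total
#' detections are skipped with a warning.
#'
#' @param mat A count [occurrence_matrix()] with genus (or other taxon)
#'   columns, e.g. from [collapse_matrix()].
#' @return A tibble with columns `row_id`, `top_taxon`, `fraction`, `class`.
#' @export
score_specificity <- function(mat) {
  m <- unclass(mat)
  total <- rowSums(m)
  zero <- total == 0
  if (any(zero)) {
    warning(sum(zero), " row(s) with zero detections skipped")
    m <- m[!zero, , drop = FALSE]
    total <- total[!zero]
  }
  if (nrow(m) == 0L) {
    return(tibble::tibble(row_id = character(), top_taxon = character(),
                          fraction = numeric(), class = character()))
  }
  top <- max.col(m, ties.method = "first")
  fraction <- unname(m[cbind(seq_len(nrow(m)), top)] / total)
  class <- ifelse(fraction == 1, "unique",
                  ifelse(fraction > 0.95, "highly_specific", "nonspecific"))
  tibble::tibble(row_id = rownames(m), top_taxon = colnames(m)[top],
                 fraction = fraction, class = class)
}

#' Rank-level overlap counts
#'
#' For every non-empty set S of taxa at the requested rank, counts the rows
#' detected in exactly the taxa of S (the numbers behind Venn/Euler
#' summaries). Exclusive counts are the singleton sets.
#'
#' @param mat A binary [occurrence_matrix()] with data-set columns.
#' @param registry Dataset registry mapping columns to taxonomy.
#' @param rank One of `"species"`, `"genus"`, `"family"`, `"suborder"`.
#' @return `list(subset_counts = named integer vector (names are taxa sets
#'   joined by "&", sorted within the set), exclusive = named integer per
#'   taxon, n_detected = number of rows detected anywhere)`.
#' @export
rank_overlap_counts <- function(mat, registry, rank) {
  collapsed <- collapse_matrix(mat, registry, rank)
  pres <- unclass(collapsed) > 0
  detected <- rowSums(pres) > 0
  sig <- apply(pres[detected, , drop = FALSE], 1, function(r) {
    paste(sort(colnames(pres)[r]), collapse = "&")
  })
  subset_counts <- table(sig)
  subset_counts <- stats::setNames(as.integer(subset_counts),
                                   names(subset_counts))
  taxa <- colnames(pres)
  exclusive <- stats::setNames(
    vapply(taxa, function(tx)
      if (tx %in% names(subset_counts)) subset_counts[[tx]] else 0L,
      integer(1)),
    taxa)
  list(subset_counts = subset_counts, exclusive = exclusive,
       n_detected = sum(detected))
}

#' Per-genus intensity statistics of a bucket
#'
#' Median, quartiles (type-7 interpolation, the R default) and Tukey
#' outliers (beyond 1.5 x IQR fences) of the member-feature intensities of
#' one bucket, grouped per genus.
#'
#' @param bucket_id The bucket to summarise.
#' @param assignment Assignment tibble from [bucket_features()].
#' @param features The feature tibble the assignment refers to.
#' @param registry Dataset registry mapping data sets to taxonomy.
#' @return A tibble with one row per genus: `n`, `median`, `q1`, `q3`,
#'   `iqr`, and list-column `outliers`.
#' @export
bucket_stats <- function(bucket_id, assignment, features, registry) {
  members <- assignment[assignment$bucket_id == bucket_id, ]
  key_m <- paste(members$dataset_id, members$feature_id)
  key_f <- paste(features$dataset_id, features$feature_id)
  rows <- features[key_f %in% key_m, ]
  genus <- map_columns_to_taxa(rows$dataset_id, registry, "genus")
  pieces <- split(rows$intensity, genus)
  dplyr::bind_rows(lapply(names(pieces), function(g) {
    x <- pieces[[g]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    out <- x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr]
    tibble::tibble(genus = g, n = length(x), median = q[2],
                   q1 = q[1], q3 = q[3], iqr = iqr, outliers = list(out))
  }))
}
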