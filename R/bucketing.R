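## Bucketing: merge preprocessed features from all data sets into
## rectangular m/z-RT buckets and build the bucket occurrence matrix.

# Greedy nearest-centroid assignment of features (in the given order) to
# buckets whose running center lies within the half-widths; a feature that
# fits no bucket seeds a new one. Returns integer bucket indices.
greedy_assign <- function(mz, rt, hw_mz, hw_rt) {
  n <- length(mz)
  assignment <- integer(n)
  c_mz <- numeric(0)
  c_rt <- numeric(0)
  c_n <- integer(0)
  for (i in seq_len(n)) {
    if (length(c_mz) > 0L) {
      d_mz <- abs(c_mz - mz[i])
      d_rt <- abs(c_rt - rt[i])
      ok <- which(d_mz <= hw_mz & d_rt <= hw_rt)
    } else {
      ok <- integer(0)
    }
    if (length(ok) == 0L) {
      c_mz <- c(c_mz, mz[i])
      c_rt <- c(c_rt, rt[i])
      c_n <- c(c_n, 1L)
      assignment[i] <- length(c_mz)
    } else {
      d <- sqrt((d_mz[ok] / hw_mz)^2 + (d_rt[ok] / hw_rt)^2)
      # nearest center; ties broken toward the earliest-created bucket
      b <- ok[which.min(d)]
      assignment[i] <- b
      c_mz[b] <- c_mz[b] + (mz[i] - c_mz[b]) / (c_n[b] + 1L)
      c_rt[b] <- c_rt[b] + (rt[i] - c_rt[b]) / (c_n[b] + 1L)
      c_n[b] <- c_n[b] + 1L
    }
  }
  assignment
}

bucket_processing_order <- function(features) {
  order(-features$intensity, features$mz, features$rt,
        features$dataset_id, features$feature_id)
}

#' Merge features into rectangular m/z-RT buckets
#'
#' Greedy centroid procedure: features from all data sets are processed in a
#' deterministic global order (descending intensity; ties by m/z, RT,
#' dataset and feature id). Each feature joins the nearest existing bucket
#' whose running-mean center lies within the half-widths (0.015 m/z, 0.1 min
#' by default), else seeds a new bucket. Bucket centers are then finalised
#' as the plain average of their member features; frozen-center passes
#' re-check membership against the final centers and re-seed violators
#' until containment holds. A fixed-grid mode (`mode = "grid"`) is provided
#' for comparison.
#'
#' @param features Preprocessed feature tibble (all data sets).
#' @param rt_width,mz_width Full bucket widths (0.2 min, 0.03 m/z).
#' @param mode `"greedy"` (default) or `"grid"`.
#' @param max_pass Maximum number of frozen-center repair passes.
#' @return `list(buckets = tibble(bucket_id, center_mz, center_rt,
#'   n_features, n_datasets), assignment = tibble(dataset_id, feature_id,
#'   bucket_id))`.
#' @export
bucket_features <- function(features, rt_width = 0.2, mz_width = 0.03,
                            mode = c("greedy", "grid"), max_pass = 10L) {
  mode <- match.arg(mode)
  features <- tibble::as_tibble(features)
  if (nrow(features) == 0L) {
    return(list(
      buckets = tibble::tibble(bucket_id = character(),
                               center_mz = numeric(), center_rt = numeric(),
                               n_features = integer(), n_datasets = integer()),
      assignment = tibble::tibble(dataset_id = character(),
                                  feature_id = character(),
                                  bucket_id = character())))
  }
  hw_mz <- mz_width / 2
  hw_rt <- rt_width / 2
  ord <- bucket_processing_order(features)
  mz <- features$mz[ord]
  rt <- features$rt[ord]
  if (mode == "grid") {
    key <- paste(floor(mz / mz_width), floor(rt / rt_width))
    assignment <- match(key, unique(key))
  } else {
    assignment <- greedy_assign(mz, rt, hw_mz, hw_rt)
    for (pass in seq_len(max_pass)) {
      cen_mz <- tapply(mz, assignment, mean)
      cen_rt <- tapply(rt, assignment, mean)
      viol <- abs(mz - cen_mz[as.character(assignment)]) > hw_mz |
        abs(rt - cen_rt[as.character(assignment)]) > hw_rt
      if (!any(viol)) break
      if (pass == max_pass) {
        # guaranteed containment: remaining violators become singletons
        assignment[viol] <- max(assignment) + seq_len(sum(viol))
        break
      }
      # re-seed violators greedily into fresh buckets (kept buckets frozen)
      sub <- greedy_assign(mz[viol], rt[viol], hw_mz, hw_rt)
      assignment[viol] <- max(assignment) + sub
      assignment <- match(assignment, sort(unique(assignment)))
    }
  }
  # stable bucket ids ordered by center (mz, rt)
  cen_mz <- as.numeric(tapply(mz, assignment, mean))
  cen_rt <- as.numeric(tapply(rt, assignment, mean))
  lev <- sort(unique(assignment))
  rank_ord <- order(cen_mz, cen_rt)
  relabel <- integer(length(lev))
  relabel[rank_ord] <- seq_along(lev)
  new_id <- relabel[match(assignment, lev)]
  ids <- sprintf("B%05d", new_id)
  buckets <- tibble::tibble(
    bucket_id = sprintf("B%05d", seq_along(lev)),
    center_mz = cen_mz[rank_ord],
    center_rt = cen_rt[rank_ord],
    n_features = as.integer(table(new_id)),
    n_datasets = as.integer(
      rowsum(as.integer(!duplicated(paste(new_id, features$dataset_id[ord]))),
             new_id)))
  assignment_tbl <- tibble::tibble(
    dataset_id = features$dataset_id[ord],
    feature_id = features$feature_id[ord],
    bucket_id = ids)
  list(buckets = buckets, assignment = assignment_tbl)
}

#' Annotate buckets as known or unknown
#'
#' A bucket is labelled known iff its center matches any library (compound,
#' adduct) position within the RT and ppm gates; no isotope gate applies at
#' bucket level.
#'
#' @param buckets Bucket tibble from [bucket_features()].
#' @param library Compound library.
#' @param tol A [match_tolerances()] (only `ppm_max` and `rt_dev_max` used).
#' @return The bucket tibble with columns `known`, `compound_name`,
#'   `adduct` (best match by |ppm| for known buckets).
#' @export
annotate_buckets <- function(buckets, library, tol = match_tolerances()) {
  targets <- adduct_targets(library)
  known <- rep(FALSE, nrow(buckets))
  best_cpd <- rep(NA_character_, nrow(buckets))
  best_add <- rep(NA_character_, nrow(buckets))
  best_ppm <- rep(Inf, nrow(buckets))
  for (i in seq_len(nrow(targets))) {
    ppm <- abs(buckets$center_mz - targets$mz[i]) / targets$mz[i] * 1e6
    hit <- ppm < tol$ppm_max &
      abs(buckets$center_rt - targets$rt[i]) <= tol$rt_dev_max
    better <- hit & ppm < best_ppm
    known <- known | hit
    best_cpd[better] <- targets$compound_name[i]
    best_add[better] <- targets$adduct[i]
    best_ppm[better] <- ppm[better]
  }
  dplyr::mutate(buckets, known = known, compound_name = best_cpd,
                adduct = best_add)
}

#' Binary bucket occurrence matrix
#'
#' Entry (b, d) is 1 iff at least one feature of data set d was assigned to
#' bucket b.
#'
#' @param assignment Assignment tibble from [bucket_features()].
#' @param dataset_ids Optional character vector fixing the column universe.
#' @return A binary [occurrence_matrix()] (rows = buckets, cols = data sets).
#' @export
build_occurrence_matrix <- function(assignment, dataset_ids = NULL) {
  buckets <- sort(unique(assignment$bucket_id))
  if (is.null(dataset_ids)) {
    dataset_ids <- sort(unique(assignment$dataset_id))
  }
  m <- matrix(0, length(buckets), length(dataset_ids),
              dimnames = list(buckets, dataset_ids))
  if (nrow(assignment) > 0L) {
    idx <- cbind(match(assignment$bucket_id, buckets),
                 match(assignment$dataset_id, dataset_ids))
    ok <- !is.na(idx[, 2])
    m[idx[ok, , drop = FALSE]] <- 1
  }
  occurrence_matrix(m, values = "binary")
}
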