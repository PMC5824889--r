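## Background filtering: polymer-impurity removal and media-blank
## subtraction, applied per data set before bucketing.

#' Remove polymer-impurity features
#'
#' Adsorber-resin polymer impurities elute between 9 and 13 min at low
#' intensity. A feature is removed iff RT lies in \[9, 13\] min AND either
#' (1) m/z in \[500, 800\] with intensity < 20000, or (2) m/z in
#' \[150, 500) or (800, 1600\] with intensity < 5000. Boundaries are
#' inclusive on the stated endpoints; the \[500, 800\] branch owns its
#' endpoints.
#'
#' @param features A feature tibble.
#' @return `list(kept =, removed =)`, both feature tibbles.
#' @export
polymer_filter <- function(features) {
  features <- tibble::as_tibble(features)
  in_rt <- features$rt >= 9 & features$rt <= 13
  mid <- features$mz >= 500 & features$mz <= 800
  flank <- (features$mz >= 150 & features$mz < 500) |
    (features$mz > 800 & features$mz <= 1600)
  removed <- in_rt & ((mid & features$intensity < 20000) |
                        (flank & features$intensity < 5000))
  list(kept = features[!removed, , drop = FALSE],
       removed = features[removed, , drop = FALSE])
}

#' Subtract media-blank background features
#'
#' A feature is removed whenever it falls in a 0.2 min and 0.03 m/z window
#' of a blank feature, read as a full-width window centered on the blank
#' feature: removed iff some blank feature satisfies |dRT| <= 0.1 min and
#' |dm/z| <= 0.015 (boundary inclusive).
#'
#' @param features A feature tibble.
#' @param blank_features Blank features (the blanks relevant to the data
#'   set's medium, already merged across its media group).
#' @param rt_window,mz_window Full window widths (min, m/z).
#' @return `list(kept =, removed =)`.
#' @export
blank_subtract <- function(features, blank_features,
                           rt_window = 0.2, mz_window = 0.03) {
  features <- tibble::as_tibble(features)
  hw_rt <- rt_window / 2
  hw_mz <- mz_window / 2
  removed <- rep(FALSE, nrow(features))
  for (i in seq_len(nrow(blank_features))) {
    removed <- removed |
      (abs(features$mz - blank_features$mz[i]) <= hw_mz &
         abs(features$rt - blank_features$rt[i]) <= hw_rt)
  }
  list(kept = features[!removed, , drop = FALSE],
       removed = features[removed, , drop = FALSE])
}

blanks_for_medium <- function(blanks, medium_id, media_groups = NULL) {
  if (is.null(media_groups)) {
    media <- medium_id                      # identity grouping
  } else {
    if (!medium_id %in% names(media_groups)) {
      stop("no media group defined for medium '", medium_id, "'",
           call. = FALSE)
    }
    media <- media_groups[[medium_id]]
  }
  sel <- blanks[blanks$medium_id %in% media, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("no blank features available for medium '", medium_id, "'",
         call. = FALSE)
  }
  sel
}

#' Preprocess one data set
#'
#' Applies the polymer filter first, then media-blank subtraction against
#' the blanks of the data set's media group, and reports the removals.
#'
#' @param features Features of a single data set (one `dataset_id`).
#' @param blanks Blank feature tibble (with `medium_id`).
#' @param media_groups Optional named list mapping each `medium_id` to the
#'   media whose blanks should be merged for it; `NULL` means identity.
#' @param rt_window,mz_window Blank-subtraction window full widths.
#' @return `list(features = kept features, report = one-row tibble with
#'   n_input, n_removed_polymer, n_removed_blank, fraction_removed)`.
#' @export
preprocess_dataset <- function(features, blanks, media_groups = NULL,
                               rt_window = 0.2, mz_window = 0.03) {
  features <- tibble::as_tibble(features)
  if (length(unique(features$dataset_id)) > 1L) {
    stop("preprocess_dataset expects a single data set", call. = FALSE)
  }
  medium <- unique(features$medium_id)
  blank_set <- blanks_for_medium(blanks, medium, media_groups)
  p <- polymer_filter(features)
  b <- blank_subtract(p$kept, blank_set, rt_window, mz_window)
  n_in <- nrow(features)
  report <- tibble::tibble(
    dataset_id = unique(features$dataset_id),
    n_input = n_in,
    n_removed_polymer = nrow(p$removed),
    n_removed_blank = nrow(b$removed),
    fraction_removed = (nrow(p$removed) + nrow(b$removed)) / max(n_in, 1L))
  list(features = b$kept, report = report)
}

#' Preprocess a whole cohort of data sets
#'
#' @param features Feature tibble over all data sets.
#' @param blanks Blank feature tibble.
#' @param media_groups See [preprocess_dataset()].
#' @param rt_window,mz_window Blank-subtraction window full widths.
#' @return `list(features = kept features (all data sets), reports = per
#'   data set filter reports)`.
#' @export
preprocess_cohort <- function(features, blanks, media_groups = NULL,
                              rt_window = 0.2, mz_window = 0.03) {
  pieces <- split(tibble::as_tibble(features), features$dataset_id)
  out <- lapply(pieces, preprocess_dataset, blanks = blanks,
                media_groups = media_groups,
                rt_window = rt_window, mz_window = mz_window)
  list(features = dplyr::bind_rows(lapply(out, `[[`, "features")),
       reports = dplyr::bind_rows(lapply(out, `[[`, "report")))
}
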