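## De-replication: annotate features with known compounds from a reference
## library by accurate m/z, retention time and isotope-pattern matching, and
## link in-source fragments to their parent ions by neutral-loss mass.

#' Matching tolerances for de-replication
#'
#' Defaults are the standard gates of the workflow: < 5 ppm m/z error
#' (strict), RT deviation not exceeding +/- 0.15 min (inclusive), and an
#' isotope-pattern fit score < 50 (strict; skipped when a feature carries no
#' isotope envelope, in which case the match is flagged lower-confidence).
#'
#' @param ppm_max Maximum |m/z error| in ppm (strict `<`).
#' @param rt_dev_max Maximum |RT deviation| in minutes (inclusive `<=`).
#' @param iso_score_max Maximum isotope-fit score (strict `<`).
#' @return A validated list of class `"match_tolerances"`.
#' @export
match_tolerances <- function(ppm_max = 5, rt_dev_max = 0.15,
                             iso_score_max = 50) {
  if (ppm_max <= 0 || rt_dev_max <= 0 || iso_score_max <= 0) {
    stop("all tolerances must be strictly positive", call. = FALSE)
  }
  structure(list(ppm_max = ppm_max, rt_dev_max = rt_dev_max,
                 iso_score_max = iso_score_max),
            class = "match_tolerances")
}

#' Match features against a compound library
#'
#' For each library compound, only its individually observed adduct types
#' are tried. A (feature, compound, adduct) match requires
#' `|ppm_error| < ppm_max`, `|rt_deviation| <= rt_dev_max` and, when the
#' feature has an isotope envelope, `iso_score < iso_score_max`.
#' `ppm_error = (mz_obs - mz_theo) / mz_theo * 1e6`. All matches are
#' retained (no unique-assignment heuristic).
#'
#' @param features A feature tibble.
#' @param library A compound library (see [read_compound_library()]).
#' @param tol A [match_tolerances()].
#' @return A tibble of matches with columns `dataset_id`, `feature_id`,
#'   `compound_name`, `family_name`, `adduct`, `ppm_error`, `rt_deviation`,
#'   `iso_score` (NA without envelope) and `low_confidence`.
#' @export
match_features <- function(features, library, tol = match_tolerances()) {
  stopifnot(inherits(tol, "match_tolerances"))
  features <- tibble::as_tibble(features)
  has_iso <- "iso1" %in% names(features) & !is.null(features$iso1)
  empty <- tibble::tibble(
    dataset_id = character(), feature_id = character(),
    compound_name = character(), family_name = character(),
    adduct = character(), ppm_error = numeric(), rt_deviation = numeric(),
    iso_score = numeric(), low_confidence = logical())
  if (nrow(features) == 0L || nrow(library) == 0L) return(empty)
  obs_iso <- if (all(ISO_COLS %in% names(features))) {
    as.matrix(features[, ISO_COLS])
  } else {
    matrix(NA_real_, nrow(features), 3L)
  }
  out <- list()
  for (i in seq_len(nrow(library))) {
    pattern <- theoretical_isotope_pattern(library$counts[[i]], n_peaks = 3L)
    theo_ab <- pattern$abundance
    for (a in library$adducts[[i]]) {
      mz_theo <- adduct_mz(library$neutral_mass[i], a)
      ppm <- (features$mz - mz_theo) / mz_theo * 1e6
      rt_dev <- features$rt - library$reference_rt[i]
      cand <- which(abs(ppm) < tol$ppm_max &
                      abs(rt_dev) <= tol$rt_dev_max)
      if (length(cand) == 0L) next
      for (j in cand) {
        ab <- obs_iso[j, ]
        ab <- ab[!is.na(ab)]
        if (length(ab) > 0L) {
          score <- isotope_fit_score(ab, theo_ab)
          if (score >= tol$iso_score_max) next
          low <- FALSE
        } else {
          score <- NA_real_
          low <- TRUE
        }
        out[[length(out) + 1L]] <- tibble::tibble(
          dataset_id = features$dataset_id[j],
          feature_id = features$feature_id[j],
          compound_name = library$compound_name[i],
          family_name = library$family_name[i],
          adduct = a, ppm_error = ppm[j], rt_deviation = rt_dev[j],
          iso_score = score, low_confidence = low)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out)
}

#' Compound-family presence across data sets
#'
#' Collapses feature-level matches to the analysis unit of the known-compound
#' survey: a compound family is present in a data set iff at least one member
#' compound was matched by at least one feature.
#'
#' @param matches A match tibble from [match_features()].
#' @param library The compound library (defines the family universe).
#' @param dataset_ids Optional character vector fixing the column set (so
#'   data sets with zero matches appear as all-zero columns).
#' @return A binary [occurrence_matrix()] (rows = families, cols = data sets).
#' @export
family_presence_matrix <- function(matches, library, dataset_ids = NULL) {
  families <- sort(unique(library$family_name))
  if (is.null(dataset_ids)) dataset_ids <- sort(unique(matches$dataset_id))
  m <- matrix(0, length(families), length(dataset_ids),
              dimnames = list(families, dataset_ids))
  if (nrow(matches) > 0L) {
    keep <- matches$dataset_id %in% dataset_ids
    idx <- cbind(match(matches$family_name[keep], families),
                 match(matches$dataset_id[keep], dataset_ids))
    m[idx] <- 1
  }
  occurrence_matrix(m, values = "binary")
}

#' Common neutral-loss table
#'
#' Monoisotopic masses computed from the bundled isotope table. Extensible:
#' bind extra rows with your own `name`/`mass` pairs.
#'
#' @return A tibble with columns `name` and `mass` (Da).
#' @export
neutral_loss_table <- function() {
  formulas <- c(H2O = "H2O", NH3 = "H3N", CO = "CO", CO2 = "CO2",
                HCOOH = "CH2O2", HPO3 = "HO3P", H3PO4 = "H3O4P")
  tibble::tibble(name = names(formulas),
                 mass = vapply(formulas, monoisotopic_mass, numeric(1)))
}

#' Link a fragment ion to its parent by neutral-loss mass
#'
#' Returns the neutral loss whose mass matches `parent_mz - fragment_mz`
#' within a ppm tolerance taken relative to the parent m/z (closest loss
#' wins when several qualify).
#'
#' @param parent_mz,fragment_mz Ion m/z values (same charge state assumed).
#' @param losses Loss table (default [neutral_loss_table()]).
#' @param ppm Tolerance on the mass difference, ppm of `parent_mz`.
#' @return The loss name, or `NA_character_` if none matches.
#' @examples
#' link_neutral_loss(515.350, 497.339) # "H2O"
#' @export
link_neutral_loss <- function(parent_mz, fragment_mz,
                              losses = neutral_loss_table(), ppm = 5) {
  delta <- parent_mz - fragment_mz
  err <- abs(delta - losses$mass)
  tol <- ppm * 1e-6 * parent_mz
  hit <- which(err <= tol)
  if (length(hit) == 0L) return(NA_character_)
  losses$name[hit[which.min(err[hit])]]
}
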