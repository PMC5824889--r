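## End-to-end pipeline: simulate -> filter -> dereplicate -> bucket ->
## collapse/specificity -> cluster -> rank-stratified distances, as a single
## configured, seeded, logged run.

#' Pipeline run configuration
#'
#' Defaults reproduce the standard analysis parameters: 5 ppm / 0.15 min /
#' iso 50 de-replication gates, 0.2 min x 0.03 m/z blank-subtraction and
#' bucketing windows, genus subsampling cap 50 / min 20 (off by default for
#' the balanced synthetic cohort), 500 bootstrap replicates and a 99%
#' confidence interval for the paired t-test.
#'
#' @param cohort A [cohort_spec()] (used when `simulate = TRUE`) or a
#'   pre-built `"chemotax_cohort"`.
#' @param tol A [match_tolerances()].
#' @param bucket_rt_width,bucket_mz_width Bucketing window full widths.
#' @param blank_rt_window,blank_mz_window Blank-subtraction window full
#'   widths.
#' @param media_groups Optional media grouping, see [preprocess_dataset()].
#' @param dereplicate,cluster,distance Stage toggles.
#' @param subsample Apply genus subsampling before the unknowns analysis.
#' @param subsample_cap,subsample_min_n Subsampling parameters.
#' @param collapse_rank Rank for the collapsed matrix and clustering.
#' @param n_boot Bootstrap replicates for clade support.
#' @param bootstrap_method `"bp"` or `"au"`.
#' @param conf_level Confidence level of the paired t-test.
#' @param test_contrasts Character vector of length 2: the contrast classes
#'   compared by the paired t-test.
#' @param seed Integer seed controlling subsampling and bootstrap (the
#'   cohort has its own seed in its spec).
#' @param out_dir Optional output directory for all artifacts.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       tol = match_tolerances(),
                       bucket_rt_width = 0.2, bucket_mz_width = 0.03,
                       blank_rt_window = 0.2, blank_mz_window = 0.03,
                       media_groups = NULL,
                       dereplicate = TRUE, cluster = TRUE, distance = TRUE,
                       subsample = FALSE,
                       subsample_cap = 50L, subsample_min_n = 20L,
                       collapse_rank = "genus",
                       n_boot = 500L,
                       bootstrap_method = "bp",
                       conf_level = 0.99,
                       test_contrasts = c("within_species",
                                          "between_genera_within_family"),
                       seed = 1L,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(length(test_contrasts) == 2L,
            all(test_contrasts %in% CONTRAST_LEVELS))
  structure(cfg, class = "run_config")
}

stage_log <- function(report, stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(msg)
  c(report, msg)
}

config_as_json <- function(config) {
  ser <- lapply(unclass(config), function(x) {
    if (inherits(x, "cohort_spec") || inherits(x, "match_tolerances")) {
      unclass(x)
    } else if (inherits(x, "chemotax_cohort")) {
      unclass(x$spec)
    } else x
  })
  jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (simulation, background
#' filtering, de-replication, bucketing, taxon collapse + specificity +
#' overlap counts, clustering with bootstrap support, rank-stratified
#' distances with the paired t-test), logging one line per stage. Identical
#' seeds give identical reports. When `config$out_dir` is set, every
#' intermediate artifact and the serialised configuration are written there
#' as plain-text files.
#'
#' @param config A [run_config()].
#' @return A list of class `"run_report"` with stage counts and the main
#'   result objects (`filter_reports`, `matches`, `buckets`,
#'   `occurrence`, `collapsed`, `specificity`, `overlap`, `clustering`,
#'   `distances`, `test`, `log`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  t0 <- proc.time()[["elapsed"]]
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(config_as_json(config), file.path(out_dir, "config.json"))
  }

  cohort <- if (inherits(config$cohort, "chemotax_cohort")) {
    config$cohort
  } else {
    simulate_cohort(config$cohort)
  }
  registry <- dataset_registry(cohort$features)
  log <- stage_log(log, "simulate", nrow(cohort$features), " features in ",
                   nrow(registry), " data sets (seed ",
                   cohort$spec$seed, ")")
  if (!is.null(out_dir)) write_cohort(cohort, file.path(out_dir, "cohort"))

  pre <- preprocess_cohort(cohort$features, cohort$blanks,
                           media_groups = config$media_groups,
                           rt_window = config$blank_rt_window,
                           mz_window = config$blank_mz_window)
  log <- stage_log(log, "filter", nrow(pre$features), " features kept, ",
                   "mean fraction removed ",
                   signif(mean(pre$reports$fraction_removed), 3),
                   " (polymer + blank windows ", config$blank_rt_window,
                   " min / ", config$blank_mz_window, " m/z)")
  if (!is.null(out_dir)) {
    write_feature_table(pre$features, file.path(out_dir, "filtered.tsv"))
    write_table_checked(pre$reports, file.path(out_dir, "filter_report.tsv"))
  }

  matches <- NULL
  family_matrix <- NULL
  if (isTRUE(config$dereplicate)) {
    matches <- match_features(pre$features, cohort$library, config$tol)
    family_matrix <- family_presence_matrix(matches, cohort$library,
                                            registry$dataset_id)
    log <- stage_log(log, "dereplicate", nrow(matches), " matches over ",
                     sum(rowSums(family_matrix) > 0), " compound families",
                     " (ppm<", config$tol$ppm_max,
                     ", rt<=", config$tol$rt_dev_max,
                     ", iso<", config$tol$iso_score_max, ")")
    if (!is.null(out_dir)) {
      write_table_checked(matches, file.path(out_dir, "matches.tsv"))
      write_matrix(family_matrix, file.path(out_dir, "family_presence.tsv"))
    }
  }

  features_used <- pre$features
  if (isTRUE(config$subsample)) {
    sel <- subsample_datasets(registry, cap = config$subsample_cap,
                              min_n = config$subsample_min_n,
                              seed = config$seed)
    features_used <- features_used[features_used$dataset_id %in% sel, ]
    log <- stage_log(log, "subsample", length(sel), " data sets selected ",
                     "(cap ", config$subsample_cap, ", min ",
                     config$subsample_min_n, ")")
  }
  bk <- bucket_features(features_used, rt_width = config$bucket_rt_width,
                        mz_width = config$bucket_mz_width)
  occurrence <- build_occurrence_matrix(bk$assignment,
                                        unique(features_used$dataset_id))
  log <- stage_log(log, "bucket", nrow(bk$buckets), " buckets from ",
                   nrow(bk$assignment), " features (widths ",
                   config$bucket_rt_width, " min / ",
                   config$bucket_mz_width, " m/z)")
  if (!is.null(out_dir)) {
    write_table_checked(bk$buckets, file.path(out_dir, "buckets.tsv"))
    write_matrix(occurrence, file.path(out_dir, "occurrence.tsv"),
                 format = "sparse")
  }

  collapsed <- collapse_matrix(occurrence, registry, config$collapse_rank)
  specificity <- score_specificity(collapsed)
  overlap <- list(
    suborder = rank_overlap_counts(occurrence, registry, "suborder"),
    family = rank_overlap_counts(occurrence, registry, "family"))
  log <- stage_log(log, "matrix", "collapsed to ", ncol(collapsed), " ",
                   config$collapse_rank, " columns; specificity classes: ",
                   paste(names(table(specificity$class)),
                         as.integer(table(specificity$class)),
                         sep = "=", collapse = ", "))
  if (!is.null(out_dir)) {
    write_matrix(collapsed, file.path(out_dir, "collapsed.tsv"))
    write_table_checked(specificity, file.path(out_dir, "specificity.tsv"))
    writeLines(jsonlite::toJSON(overlap, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "overlap_counts.json"))
  }

  clustering <- NULL
  if (isTRUE(config$cluster)) {
    clustering <- bootstrap_support(collapsed, n_boot = config$n_boot,
                                    method = config$bootstrap_method,
                                    seed = config$seed)
    log <- stage_log(log, "cluster", "UPGMA over ", ncol(collapsed),
                     " profiles, ", config$n_boot, " bootstrap replicates (",
                     config$bootstrap_method, ")")
    if (!is.null(out_dir)) {
      write_newick(clustering, file.path(out_dir, "dendrogram.nwk"))
      write_table_checked(clustering$support,
                          file.path(out_dir, "clade_support.tsv"))
    }
  }

  distances <- NULL
  test <- NULL
  if (isTRUE(config$distance)) {
    distances <- rank_stratified_distances(occurrence, registry)
    test <- paired_profile_test(distances$distances,
                                contrast_a = config$test_contrasts[1],
                                contrast_b = config$test_contrasts[2],
                                conf_level = config$conf_level)
    log <- stage_log(log, "distance", nrow(distances$distances),
                     " pairs; paired t-test ", config$test_contrasts[1],
                     " vs ", config$test_contrasts[2], ": p = ",
                     format(test$p_value, digits = 3), " (",
                     config$conf_level * 100, "% CI)")
    if (!is.null(out_dir)) {
      write_table_checked(distances$histogram,
                          file.path(out_dir, "distance_histograms.tsv"))
      write_table_checked(distances$summary,
                          file.path(out_dir, "distance_summary.tsv"))
      writeLines(jsonlite::toJSON(as.list(test), auto_unbox = TRUE,
                                  digits = NA),
                 file.path(out_dir, "paired_test.json"))
    }
  }

  structure(list(
    n_datasets = nrow(registry),
    n_features = nrow(cohort$features),
    n_features_filtered = nrow(pre$features),
    n_buckets = nrow(bk$buckets),
    filter_reports = pre$reports,
    matches = matches, family_matrix = family_matrix,
    buckets = bk$buckets, assignment = bk$assignment,
    occurrence = occurrence, collapsed = collapsed,
    specificity = specificity, overlap = overlap,
    clustering = clustering, distances = distances, test = test,
    elapsed = proc.time()[["elapsed"]] - t0,
    log = log), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", x$n_datasets, "data sets;", x$n_features,
      "features ->", x$n_features_filtered, "filtered ->", x$n_buckets,
      "buckets;", if (!is.null(x$test))
        paste0("paired t-test p = ", format(x$test$p_value, digits = 3)),
      "\n")
  invisible(x)
}
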