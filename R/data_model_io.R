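## Core tabular data model and file I/O shared by the pipeline.
##
## A cohort is represented by two tidy tables:
##   * a feature table: one row per LC-MS feature, keyed by
##     (dataset_id, feature_id), carrying m/z, RT (min), intensity and an
##     optional 3-peak isotope envelope (iso1..iso3, base peak normalised);
##   * a dataset registry: one row per data set with its strain taxonomy
##     (suborder > family > genus > species > strain) and cultivation medium.
## Feature files on disk are flat TSV/CSV with both blocks of columns joined.

MZ_RANGE <- c(150, 2500)   # instrument acquisition range, m/z
RT_RANGE <- c(0.5, 20.5)   # feature annotation window, minutes
ISO_COLS <- c("iso1", "iso2", "iso3")
SPECIES_UNCLASSIFIED <- "unclassified"

FEATURE_META_COLS <- c("dataset_id", "strain_id", "suborder", "family",
                       "genus", "species", "medium_id")
FEATURE_DATA_COLS <- c("feature_id", "mz", "rt", "intensity")

#' Validate a feature table
#'
#' Checks required columns, m/z and RT ranges, positive intensities and
#' uniqueness of `feature_id` within each data set. Errors name offending
#' row numbers.
#'
#' @param features A data frame of features (see [read_feature_table()]).
#' @param require_meta Require the dataset/taxonomy metadata columns too.
#' @return The validated table as a tibble, invisibly usable in pipes.
#' @export
validate_features <- function(features, require_meta = TRUE) {
  features <- tibble::as_tibble(features)
  need <- c(if (require_meta) FEATURE_META_COLS, FEATURE_DATA_COLS)
  missing <- setdiff(need, names(features))
  if (length(missing) > 0L) {
    stop("feature table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(features$mz < MZ_RANGE[1] | features$mz > MZ_RANGE[2] |
                 is.na(features$mz))
  if (length(bad) > 0L) {
    stop("m/z outside [", MZ_RANGE[1], ", ", MZ_RANGE[2], "] in rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(features$rt < RT_RANGE[1] | features$rt > RT_RANGE[2] |
                 is.na(features$rt))
  if (length(bad) > 0L) {
    stop("RT outside [", RT_RANGE[1], ", ", RT_RANGE[2], "] min in rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!(features$intensity > 0))
  if (length(bad) > 0L) {
    stop("non-positive intensity in rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(features$dataset_id, features$feature_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate feature_id within a data set in rows: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  features
}

#' Extract the dataset registry from a feature table
#'
#' @param features A feature table with metadata columns.
#' @return One row per dataset_id with strain taxonomy and medium.
#' @export
dataset_registry <- function(features) {
  out <- dplyr::distinct(
    tibble::as_tibble(features),
    dplyr::across(dplyr::all_of(FEATURE_META_COLS)))
  if (anyDuplicated(out$dataset_id)) {
    stop("inconsistent metadata within a dataset_id", call. = FALSE)
  }
  out
}

#' Validate a taxonomy registry
#'
#' One row per strain with columns `strain_id`, `species`, `genus`,
#' `family`, `suborder`. Checks uniqueness of strain ids, non-empty ranks
#' and that genus->family and family->suborder mappings are functions
#' (violations reported with the strain ids involved). The species value
#' `"unclassified"` is an allowed sentinel.
#'
#' @param taxonomy A data frame.
#' @return The validated tibble.
#' @export
validate_taxonomy <- function(taxonomy) {
  taxonomy <- tibble::as_tibble(taxonomy)
  need <- c("strain_id", "species", "genus", "family", "suborder")
  missing <- setdiff(need, names(taxonomy))
  if (length(missing) > 0L) {
    stop("taxonomy is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(taxonomy$strain_id)) {
    stop("duplicate strain_id in taxonomy registry", call. = FALSE)
  }
  for (col in need) {
    if (any(is.na(taxonomy[[col]]) | !nzchar(taxonomy[[col]]))) {
      stop("empty values in taxonomy column '", col, "'", call. = FALSE)
    }
  }
  check_function <- function(from, to) {
    map <- dplyr::distinct(taxonomy[, c(from, to)])
    dup <- map[[from]][duplicated(map[[from]])]
    if (length(dup) > 0L) {
      bad <- taxonomy$strain_id[taxonomy[[from]] %in% dup]
      stop("taxonomy rank mapping ", from, " -> ", to,
           " is not a function; strains involved: ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
  }
  check_function("genus", "family")
  check_function("family", "suborder")
  sp <- taxonomy[taxonomy$species != SPECIES_UNCLASSIFIED, ]
  map <- dplyr::distinct(sp[, c("species", "genus")])
  dup <- map$species[duplicated(map$species)]
  if (length(dup) > 0L) {
    stop("species assigned to multiple genera: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  taxonomy
}

## Low-level table reading with footer row-count check ----------------------

table_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_checked <- function(path) {
  lines <- readLines(path)
  footer <- grep("^#\\s*rows:", lines, value = TRUE)
  data_lines <- lines[!grepl("^#", lines)]
  data_lines <- data_lines[nzchar(data_lines)]
  tab <- utils::read.table(text = paste(data_lines, collapse = "\n"),
                           header = TRUE, sep = table_sep(path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (length(footer) > 0L) {
    expected <- as.integer(sub("^#\\s*rows:\\s*", "", footer[length(footer)]))
    if (!is.na(expected) && nrow(tab) != expected) {
      stop("file appears truncated: footer declares ", expected,
           " rows but ", nrow(tab), " were read from ", path, call. = FALSE)
    }
  }
  tibble::as_tibble(tab)
}

write_table_checked <- function(x, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(x, con, sep = table_sep(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  writeLines(paste0("# rows: ", nrow(x)), con)
  invisible(path)
}

## Feature tables -----------------------------------------------------------

#' Read a feature table
#'
#' Reads a TSV/CSV feature file (columns `dataset_id`, `strain_id`,
#' `suborder`, `family`, `genus`, `species`, `medium_id`, `feature_id`,
#' `mz`, `rt`, `intensity`, optional `iso1..iso3`), validates invariants and
#' checks the `# rows:` footer when present.
#'
#' @param path Path to a `.tsv` or `.csv` file.
#' @return A validated feature tibble.
#' @export
read_feature_table <- function(path) {
  tab <- read_table_checked(path)
  for (col in intersect(ISO_COLS, names(tab))) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  validate_features(tab)
}

#' Write a feature table
#'
#' @param features A feature tibble.
#' @param path Output path (`.tsv` or `.csv`); a `# rows:` footer is
#'   appended so truncated files are detectable.
#' @export
write_feature_table <- function(features, path) {
  validate_features(features)
  keep <- c(FEATURE_META_COLS, FEATURE_DATA_COLS,
            intersect(ISO_COLS, names(features)))
  write_table_checked(features[, keep], path)
}

#' Read / write a taxonomy registry
#'
#' @param path Path to a TSV/CSV with columns `strain_id`, `species`,
#'   `genus`, `family`, `suborder` (a `medium_id` column is carried along
#'   when present).
#' @return `read_taxonomy()` returns the validated tibble.
#' @export
read_taxonomy <- function(path) {
  validate_taxonomy(read_table_checked(path))
}

#' @rdname read_taxonomy
#' @param taxonomy The registry tibble to write.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write_table_checked(validate_taxonomy(taxonomy), path)
}

## Compound library ---------------------------------------------------------

#' Read a compound reference library
#'
#' File columns: `compound_name`, `family_name`, `formula`, `reference_rt`
#' (minutes) and `adducts` (semicolon-separated adduct names from
#' [adduct_table()]). Formulas are parsed and the neutral monoisotopic mass
#' is precomputed. Duplicate compound names, unparsable formulas, unknown
#' adduct names and empty adduct lists are errors.
#'
#' @param path Path to a `.tsv` or `.csv` file.
#' @return A tibble with list-columns `counts` (element counts) and
#'   `adducts` (character vectors) plus `neutral_mass`.
#' @export
read_compound_library <- function(path) {
  tab <- read_table_checked(path)
  need <- c("compound_name", "family_name", "formula", "reference_rt",
            "adducts")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("compound library is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_compound_library(tibble::tibble(
    compound_name = as.character(tab$compound_name),
    family_name = as.character(tab$family_name),
    formula = as.character(tab$formula),
    reference_rt = as.numeric(tab$reference_rt),
    adducts = strsplit(normalize_minus(as.character(tab$adducts)), ";")))
}

#' Validate a compound library tibble
#'
#' @param library A tibble with columns `compound_name`, `family_name`,
#'   `formula`, `reference_rt` and list-column `adducts`.
#' @return The library with `counts` and `neutral_mass` columns filled in.
#' @export
validate_compound_library <- function(library) {
  library <- tibble::as_tibble(library)
  if (anyDuplicated(library$compound_name)) {
    stop("duplicate compound_name in library", call. = FALSE)
  }
  library$adducts <- lapply(library$adducts, function(a) {
    a <- trimws(normalize_minus(a))
    a[nzchar(a)]
  })
  n_add <- vapply(library$adducts, length, integer(1))
  if (any(n_add == 0L)) {
    stop("compound(s) with empty adduct list: ",
         paste(utils::head(library$compound_name[n_add == 0L], 5),
               collapse = ", "), call. = FALSE)
  }
  known <- adduct_table()$name
  for (i in seq_len(nrow(library))) {
    bad <- setdiff(library$adducts[[i]], known)
    if (length(bad) > 0L) {
      stop("unknown adduct name for ", library$compound_name[i], ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  library$counts <- lapply(library$formula, parse_formula)
  library$neutral_mass <- vapply(library$counts, monoisotopic_mass,
                                 numeric(1))
  library
}

#' @rdname read_compound_library
#' @param library The library tibble to write.
#' @export
write_compound_library <- function(library, path) {
  library <- validate_compound_library(library)
  out <- tibble::tibble(
    compound_name = library$compound_name,
    family_name = library$family_name,
    formula = library$formula,
    reference_rt = library$reference_rt,
    adducts = vapply(library$adducts, paste, character(1), collapse = ";"))
  write_table_checked(out, path)
}

## Occurrence matrices ------------------------------------------------------

#' Construct an occurrence matrix
#'
#' A plain numeric matrix (rows = buckets or compound families, columns =
#' data sets or taxa) with `values` ("binary" or "count") and an optional
#' column-rank label stored as attributes.
#'
#' @param mat Numeric matrix with row and column names.
#' @param values `"binary"` or `"count"`.
#' @param rank Taxonomic rank of the columns, or `NA`.
#' @return The matrix with class `"occurrence_matrix"`.
#' @export
occurrence_matrix <- function(mat, values = c("binary", "count"),
                              rank = NA_character_) {
  values <- match.arg(values)
  stopifnot(is.matrix(mat))
  if (is.null(rownames(mat)) && nrow(mat) > 0) {
    stop("occurrence matrix needs row names", call. = FALSE)
  }
  if (is.null(colnames(mat)) && ncol(mat) > 0) {
    stop("occurrence matrix needs column names", call. = FALSE)
  }
  if (values == "binary" && nrow(mat) > 0 && !all(mat %in% c(0, 1))) {
    stop("binary occurrence matrix must contain only 0/1", call. = FALSE)
  }
  structure(mat, values = values, rank = rank,
            class = c("occurrence_matrix", "matrix", "array"))
}

#' Write / read an occurrence matrix
#'
#' Two lossless plain-text dialects: `"dense"` (TSV, first column `row_id`)
#' and `"sparse"` (coordinate triplets `row_id`, `col_id`, `value`, with the
#' full row/column id sets recorded in header comments so empty rows and
#' columns survive the round trip).
#'
#' @param mat An occurrence matrix (see [occurrence_matrix()]).
#' @param path Output path.
#' @param format `"dense"` or `"sparse"`.
#' @export
write_matrix <- function(mat, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  values <- attr(mat, "values") %||% "count"
  rank <- attr(mat, "rank") %||% NA_character_
  meta <- c(paste0("format: ", format),
            paste0("values: ", values),
            paste0("rank: ", ifelse(is.na(rank), "NA", rank)))
  if (format == "dense") {
    df <- data.frame(row_id = rownames(mat),
                     as.data.frame(unclass(mat), check.names = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_table_checked(df, path, comments = meta)
  } else {
    idx <- which(unclass(mat) != 0, arr.ind = TRUE)
    ri <- rownames(mat) %||% character(0)
    ci <- colnames(mat) %||% character(0)
    df <- data.frame(row_id = ri[idx[, 1]],
                     col_id = ci[idx[, 2]],
                     value = mat[idx], stringsAsFactors = FALSE)
    df <- df[order(df$row_id, df$col_id), , drop = FALSE]
    meta <- c(meta,
              paste0("row_ids: ", paste(rownames(mat), collapse = ",")),
              paste0("col_ids: ", paste(colnames(mat), collapse = ",")))
    write_table_checked(df, path, comments = meta)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @return `read_matrix()` returns the reconstructed occurrence matrix.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  comments <- lines[grepl("^#", lines)]
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), comments, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    sub(paste0("^#\\s*", key, ":\\s*"), "", hit[1])
  }
  format <- get_meta("format")
  values <- get_meta("values")
  rank <- get_meta("rank")
  tab <- read_table_checked(path)
  if (is.na(format)) {
    format <- if (identical(names(tab), c("row_id", "col_id", "value")))
      "sparse" else "dense"
  }
  if (format == "dense") {
    if (names(tab)[1] != "row_id") {
      stop("dense matrix file must start with a row_id column", call. = FALSE)
    }
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab$row_id)
  } else {
    row_ids <- strsplit(get_meta("row_ids"), ",")[[1]]
    col_ids <- strsplit(get_meta("col_ids"), ",")[[1]]
    if (anyNA(row_ids) || anyNA(col_ids)) {
      stop("sparse matrix file lacks row_ids/col_ids headers", call. = FALSE)
    }
    m <- matrix(0, nrow = length(row_ids), ncol = length(col_ids),
                dimnames = list(row_ids, col_ids))
    if (nrow(tab) > 0) {
      ri <- match(as.character(tab$row_id), row_ids)
      ci <- match(as.character(tab$col_id), col_ids)
      if (anyNA(ri) || anyNA(ci)) {
        stop("sparse matrix entry references an unknown row/column id",
             call. = FALSE)
      }
      m[cbind(ri, ci)] <- tab$value
    }
  }
  if (is.na(values) || !values %in% c("binary", "count")) {
    values <- if (nrow(m) == 0 || all(m %in% c(0, 1))) "binary" else "count"
  }
  occurrence_matrix(m, values = values,
                    rank = if (identical(rank, "NA")) NA_character_ else rank)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
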