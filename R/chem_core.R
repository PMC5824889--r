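#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Shared constants ---------------------------------------------------------

#' Proton mass used throughout adduct arithmetic, in Da.
#' @export
PROTON_MASS <- 1.00727646

.chemotax_env <- new.env(parent = emptyenv())

normalize_minus <- function(x) {
  # accept the typographic minus (U+2212) in adduct names and formulas
  gsub("−", "-", x)
}

#' Bundled stable-isotope table
#'
#' Monoisotopic masses and natural abundances for the elements supported by
#' the formula parser. The table ships as a plain-text file under
#' `extdata/isotopes.tsv` so it is auditable; a different table can be used
#' for one call via the `table` argument of the chem functions.
#'
#' @return A data frame with columns `element`, `mass` (Da), `abundance`.
#' @export
isotope_table <- function() {
  if (is.null(.chemotax_env$isotopes)) {
    path <- system.file("extdata", "isotopes.tsv", package = "chemotax",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    stopifnot(all(c("element", "mass", "abundance") %in% names(tab)))
    .chemotax_env$isotopes <- tab
  }
  .chemotax_env$isotopes
}

#' Bundled adduct definitions
#'
#' Ion types with their mass delta (Da), signed charge and multiplicity of M,
#' such that m/z = (mult * M + delta) / |charge|. Electron mass is neglected
#' in the metal and ammonium deltas (documented in the data file).
#'
#' @return A data frame with columns `name`, `delta`, `charge`, `mult`.
#' @export
adduct_table <- function() {
  if (is.null(.chemotax_env$adducts)) {
    path <- system.file("extdata", "adducts.tsv", package = "chemotax",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    stopifnot(all(c("name", "delta", "charge", "mult") %in% names(tab)))
    .chemotax_env$adducts <- tab
  }
  .chemotax_env$adducts
}

lookup_adduct <- function(adduct) {
  tab <- adduct_table()
  if (is.character(adduct)) {
    adduct <- normalize_minus(adduct)
    i <- match(adduct, tab$name)
    if (anyNA(i)) {
      stop("unknown adduct name: ",
           paste(adduct[is.na(i)], collapse = ", "), call. = FALSE)
    }
    tab[i, , drop = FALSE]
  } else if (is.list(adduct) &&
             all(c("delta", "charge", "mult") %in% names(adduct))) {
    as.data.frame(adduct, stringsAsFactors = FALSE)
  } else {
    stop("adduct must be an adduct name or a list(delta, charge, mult)",
         call. = FALSE)
  }
}

## Element counts -----------------------------------------------------------

as_element_counts <- function(counts) {
  if (is.character(counts) && length(counts) == 1L) {
    return(parse_formula(counts))
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("element counts must be a named vector", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    stop("formula must contain at least one atom", call. = FALSE)
  }
  known <- unique(isotope_table()$element)
  unknown <- setdiff(names(counts), known)
  if (length(unknown) > 0L) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Parse a molecular formula
#'
#' Parses a Hill-notation-like formula string (capitalised element symbols,
#' optional integer counts) into a named integer vector of element counts.
#'
#' @param text A single formula string, e.g. `"C35H47O7P"`.
#' @return Named integer vector of element counts (elements sorted
#'   alphabetically; duplicate symbols are summed).
#' @examples
#' parse_formula("C35H47O7P")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string", call. = FALSE)
  }
  text <- gsub("\\s", "", normalize_minus(text))
  if (!nzchar(text)) stop("empty formula string", call. = FALSE)
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (paste(tokens, collapse = "") != text) {
    residue <- text
    for (tk in tokens) residue <- sub(tk, "", residue, fixed = TRUE)
    stop("malformed formula near '", substr(residue, 1, 5), "' in '",
         text, "'", call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(cnt == "", "1", cnt)
  cnt <- suppressWarnings(as.integer(cnt))
  if (anyNA(cnt) || any(cnt < 1)) {
    stop("malformed count in formula '", text, "'", call. = FALSE)
  }
  known <- unique(isotope_table()$element)
  unknown <- setdiff(sym, known)
  if (length(unknown) > 0L) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  agg <- tapply(cnt, sym, sum)
  out <- as.integer(agg)
  names(out) <- names(agg)
  out
}

#' Format element counts as a Hill-notation formula
#'
#' @param counts Named integer vector of element counts.
#' @return A formula string: carbon first, then hydrogen, then the remaining
#'   elements alphabetically (plain alphabetical when no carbon).
#' @export
format_formula <- function(counts) {
  counts <- as_element_counts(counts)
  sym <- names(counts)
  if ("C" %in% sym) {
    ord <- c(intersect(c("C", "H"), sym), sort(setdiff(sym, c("C", "H"))))
  } else {
    ord <- sort(sym)
  }
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

## Masses and adduct m/z ----------------------------------------------------

#' Monoisotopic mass of a molecular formula
#'
#' Sum of the most-abundant-isotope masses over all atoms.
#'
#' @param counts Named integer vector of element counts, or a formula string.
#' @return Mass in Da (full precision; round to 4 d.p. for reporting).
#' @examples
#' monoisotopic_mass("C35H47O7P") # 610.3059
#' @export
monoisotopic_mass <- function(counts) {
  counts <- as_element_counts(counts)
  iso <- isotope_table()
  iso <- iso[order(-iso$abundance), ]
  principal <- iso[!duplicated(iso$element), ]
  m <- principal$mass[match(names(counts), principal$element)]
  sum(m * counts)
}

#' m/z of an adduct ion
#'
#' @param neutral_mass Neutral monoisotopic mass M in Da (may be a vector).
#' @param adduct Adduct name from [adduct_table()] (e.g. `"[M+H]+"`) or a
#'   `list(delta =, charge =, mult =)`.
#' @return m/z = (mult * M + delta) / |charge|.
#' @examples
#' adduct_mz(610.3059404, "[M+H]+") # 611.3132
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (any(neutral_mass <= 0)) stop("neutral_mass must be > 0", call. = FALSE)
  a <- lookup_adduct(adduct)
  if (nrow(a) != 1L) stop("adduct_mz takes a single adduct", call. = FALSE)
  if (a$charge == 0) stop("adduct charge must be nonzero", call. = FALSE)
  (a$mult * neutral_mass + a$delta) / abs(a$charge)
}

## Isotope patterns ---------------------------------------------------------

# Distribution over integer isotopologue groups for one element:
# list(p = abundance per group, d = abundance-weighted exact mass offset).
element_distribution <- function(element, iso) {
  rows <- iso[iso$element == element, , drop = FALSE]
  rows <- rows[order(rows$mass), ]
  k <- as.integer(round(rows$mass - rows$mass[1]))
  p <- numeric(max(k) + 1L)
  d <- numeric(max(k) + 1L)
  p[k + 1L] <- rows$abundance / sum(rows$abundance)
  d[k + 1L] <- rows$mass - rows$mass[1]
  list(p = p, d = d)
}

# Convolve two isotopologue distributions, tracking the abundance-weighted
# mean exact-mass offset per group; prune negligible tail mass.
convolve_dist <- function(a, b, prune = 1e-12, max_groups = 64L) {
  na <- length(a$p); nb <- length(b$p)
  p <- numeric(na + nb - 1L)
  w <- numeric(na + nb - 1L)
  for (i in seq_len(na)) {
    if (a$p[i] == 0) next
    idx <- i:(i + nb - 1L)
    contrib <- a$p[i] * b$p
    p[idx] <- p[idx] + contrib
    w[idx] <- w[idx] + contrib * (a$d[i] + b$d)
  }
  d <- ifelse(p > 0, w / p, 0)
  keep <- max(which(p > prune * sum(p)))
  keep <- min(keep, max_groups)
  list(p = p[seq_len(keep)], d = d[seq_len(keep)])
}

dist_power <- function(base, n) {
  result <- NULL
  while (n > 0L) {
    if (n %% 2L == 1L) {
      result <- if (is.null(result)) base else convolve_dist(result, base)
    }
    base <- convolve_dist(base, base)
    n <- n %/% 2L
  }
  if (is.null(result)) list(p = 1, d = 0) else result
}

#' Theoretical isotope pattern of a molecular formula
#'
#' Convolves the per-element natural isotope distributions into isotopologue
#' groups (A, A+1, A+2, ...), prunes groups below `1e-4` relative abundance
#' and truncates to `n_peaks` groups. Abundances are normalised so the base
#' peak equals 1; offsets are abundance-weighted exact mass offsets from the
#' monoisotopic peak.
#'
#' @param counts Named integer vector of element counts, or a formula string.
#' @param n_peaks Maximum number of isotopologue groups to return.
#' @return A tibble with columns `offset` (Da) and `abundance` (base peak 1).
#' @examples
#' theoretical_isotope_pattern("C10", n_peaks = 2)
#' @export
theoretical_isotope_pattern <- function(counts, n_peaks = 3L) {
  counts <- as_element_counts(counts)
  stopifnot(n_peaks >= 1L)
  iso <- isotope_table()
  acc <- NULL
  for (el in names(counts)) {
    pw <- dist_power(element_distribution(el, iso), counts[[el]])
    acc <- if (is.null(acc)) pw else convolve_dist(acc, pw)
  }
  rel <- acc$p / max(acc$p)
  keep <- rel >= 1e-4
  keep[1] <- TRUE  # monoisotopic group is always reported
  # truncate to the first n_peaks *retained* groups
  idx <- which(keep)[seq_len(min(n_peaks, sum(keep)))]
  ab <- rel[idx] / max(rel[idx])
  tibble::tibble(offset = acc$d[idx], abundance = ab)
}

pattern_abundances <- function(pattern) {
  if (is.data.frame(pattern)) {
    if (!"abundance" %in% names(pattern)) {
      stop("isotope pattern needs an 'abundance' column", call. = FALSE)
    }
    ab <- pattern$abundance
  } else {
    ab <- as.numeric(pattern)
  }
  ab <- ab[!is.na(ab)]
  if (length(ab) == 0L) stop("empty isotope pattern", call. = FALSE)
  if (any(ab <= 0) || any(ab > 1 + 1e-9)) {
    stop("isotope abundances must lie in (0, 1]", call. = FALSE)
  }
  ab
}

#' Isotope-pattern fit score
#'
#' Dissimilarity between an observed and a theoretical isotope pattern:
#' 1000 times the root-mean-square difference of the base-peak-normalised
#' abundances over the first k = min(length) isotopologue groups. Zero means
#' identical patterns; lower is better. This plays the role of the vendor
#' "mSigma" unit with the same scale intuition; numerical agreement with any
#' vendor score is not claimed.
#'
#' @param observed,theoretical Isotope patterns: tibbles with an `abundance`
#'   column, or plain numeric abundance vectors (base peak = 1).
#' @return Non-negative dimensionless score; symmetric in its arguments.
#' @examples
#' isotope_fit_score(c(1, 0.40), c(1, 0.38)) # ~14.14
#' @export
isotope_fit_score <- function(observed, theoretical) {
  a <- pattern_abundances(observed)
  b <- pattern_abundances(theoretical)
  k <- min(length(a), length(b))
  1000 * sqrt(mean((a[seq_len(k)] - b[seq_len(k)])^2))
}
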