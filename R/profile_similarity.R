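## Rank-stratified profile similarity: bitvector cosine distances between
## binary metabolite profiles, grouped by the taxonomic relation of the
## strain pair, with paired t-tests between contrast classes.

CONTRAST_LEVELS <- c("within_species", "between_species_within_genus",
                     "between_genera_within_family", "between_suborders")

#' Bitvector cosine distance between two binary profiles
#'
#' `1 - |a AND b| / sqrt(|a| |b|)`. Zero-vector conventions: distance 1
#' against a non-zero profile, 0 between two zero profiles.
#'
#' @param a,b Binary profiles of equal length (logical or 0/1 numeric).
#' @return Distance in \[0, 1\].
#' @examples
#' cosine_distance(c(1, 1, 0), c(1, 0, 1)) # 0.5
#' @export
cosine_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length", call. = FALSE)
  a <- as.numeric(a) > 0
  b <- as.numeric(b) > 0
  na <- sum(a)
  nb <- sum(b)
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) return(1)
  min(max(1 - sum(a & b) / sqrt(na * nb), 0), 1)
}

#' Taxonomic contrast class of a strain pair
#'
#' Returns which of the four analysis series a pair of strains belongs to:
#' `within_species` (same named species), `between_species_within_genus`
#' (same genus, different named species), `between_genera_within_family`
#' (same family, different genera), `between_suborders`, or `NA` for pairs
#' in none of the four series (same suborder but different families, and
#' same-genus pairs whose species relation is unknowable because either
#' strain is `"unclassified"`).
#'
#' @param t1,t2 One-row tibbles (or named lists) with `species`, `genus`,
#'   `family`, `suborder`.
#' @return A contrast label or `NA_character_`.
#' @export
classify_pair <- function(t1, t2) {
  classify_pair_vec(t1$species, t2$species, t1$genus, t2$genus,
                    t1$family, t2$family, t1$suborder, t2$suborder)
}

classify_pair_vec <- function(sp1, sp2, g1, g2, f1, f2, so1, so2) {
  unclassified <- sp1 == SPECIES_UNCLASSIFIED | sp2 == SPECIES_UNCLASSIFIED
  out <- rep(NA_character_, length(sp1))
  out[g1 == g2 & sp1 == sp2 & !unclassified] <- "within_species"
  out[g1 == g2 & sp1 != sp2 & !unclassified] <- "between_species_within_genus"
  out[g1 != g2 & f1 == f2] <- "between_genera_within_family"
  out[so1 != so2] <- "between_suborders"
  out
}

#' Rank-stratified cosine-distance distributions
#'
#' Computes the bitvector cosine distance between every unordered pair of
#' data-set columns, assigns each pair its taxonomic contrast class, and
#' returns the per-class distance distributions with binned histograms
#' (both frequency and density normalised).
#'
#' @param mat A binary [occurrence_matrix()] with data-set columns.
#' @param registry Dataset registry mapping columns to strain taxonomy.
#' @param bin_width Histogram bin width on \[0, 1\] (default 0.05).
#' @return `list(distances = tibble(dataset_a, dataset_b, strain_a,
#'   strain_b, label, distance), histogram = tibble(label, bin_lo, bin_hi,
#'   count, density), summary = tibble(label, n_pairs, mean, sd))`.
#' @export
rank_stratified_distances <- function(mat, registry, bin_width = 0.05) {
  ids <- colnames(mat)
  i <- match(ids, registry$dataset_id)
  if (anyNA(i)) stop("columns without taxonomy", call. = FALSE)
  reg <- registry[i, ]
  D <- as.matrix(profile_distance_matrix(mat, "cosine"))
  pairs <- utils::combn(length(ids), 2)
  a <- pairs[1, ]
  b <- pairs[2, ]
  label <- classify_pair_vec(reg$species[a], reg$species[b],
                             reg$genus[a], reg$genus[b],
                             reg$family[a], reg$family[b],
                             reg$suborder[a], reg$suborder[b])
  label[reg$strain_id[a] == reg$strain_id[b]] <- NA_character_
  distances <- tibble::tibble(
    dataset_a = ids[a], dataset_b = ids[b],
    strain_a = reg$strain_id[a], strain_b = reg$strain_id[b],
    label = label, distance = D[cbind(a, b)])
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  classified <- distances[!is.na(distances$label), ]
  histogram <- dplyr::bind_rows(lapply(
    intersect(CONTRAST_LEVELS, unique(classified$label)), function(lv) {
      x <- classified$distance[classified$label == lv]
      h <- graphics::hist(x, breaks = breaks, plot = FALSE)
      tibble::tibble(label = lv, bin_lo = utils::head(h$breaks, -1),
                     bin_hi = h$breaks[-1], count = h$counts,
                     density = h$density)
    }))
  summary <- dplyr::summarise(
    dplyr::group_by(classified, .data$label),
    n_pairs = dplyr::n(), mean = mean(.data$distance),
    sd = stats::sd(.data$distance), .groups = "drop")
  list(distances = distances, histogram = histogram, summary = summary)
}

#' Paired t-test between two contrast classes
#'
#' Pairing unit is the strain: every strain with at least one pair in both
#' contrasts contributes the pair (its mean distance in contrast A, its mean
#' distance in contrast B); the standard two-sided paired t statistic is
#' computed on the per-strain differences with a 99% confidence interval by
#' default. An unpaired Welch test is available behind `paired = FALSE`.
#'
#' @param distances The `distances` tibble from
#'   [rank_stratified_distances()].
#' @param contrast_a,contrast_b Contrast labels (see `CONTRAST_LEVELS`).
#' @param conf_level Confidence level for the mean-difference CI.
#' @param paired Set `FALSE` for an unpaired Welch test on the per-strain
#'   means.
#' @return A one-row tibble: `t`, `df`, `p_value`, `conf_low`, `conf_high`,
#'   `estimate` (mean difference A - B), `n_pairs`, `conf_level`.
#' @export
paired_profile_test <- function(distances,
                                contrast_a = "within_species",
                                contrast_b = "between_genera_within_family",
                                conf_level = 0.99, paired = TRUE) {
  strain_means <- function(contrast) {
    d <- distances[!is.na(distances$label) & distances$label == contrast, ]
    long <- rbind(data.frame(strain = d$strain_a, distance = d$distance),
                  data.frame(strain = d$strain_b, distance = d$distance))
    tapply(long$distance, long$strain, mean)
  }
  ma <- strain_means(contrast_a)
  mb <- strain_means(contrast_b)
  common <- intersect(names(ma), names(mb))
  if (length(common) < 2L) {
    stop("fewer than 2 strains with pairs in both contrasts", call. = FALSE)
  }
  x <- as.numeric(ma[common])
  y <- as.numeric(mb[common])
  if (paired && stats::sd(x - y) == 0) {
    if (all(x == y)) {
      # identical per-strain means: no evidence of any difference
      return(tibble::tibble(
        contrast_a = contrast_a, contrast_b = contrast_b,
        t = 0, df = length(common) - 1, p_value = 1,
        conf_low = 0, conf_high = 0, estimate = 0,
        n_pairs = length(common), conf_level = conf_level))
    }
    stop("degenerate paired test: zero variance of differences",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = paired, conf.level = conf_level)
  tibble::tibble(
    contrast_a = contrast_a, contrast_b = contrast_b,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, conf_low = tt$conf.int[1],
    conf_high = tt$conf.int[2], estimate = unname(tt$estimate[1]),
    n_pairs = length(common), conf_level = conf_level)
}
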