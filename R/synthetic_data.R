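## Synthetic cohort generator.
##
## Emulates the statistical structure the downstream analysis assumes:
## a taxonomically structured set of strains (suborder > family > genus >
## species > strain), genus-typical cultivation media, compound families
## planted at different taxonomic scopes (species-, genus-, family-,
## suborder-specific and cosmopolitan), several adduct ions (optionally an
## in-source water-loss fragment) per compound, medium-specific background
## features shared by all data sets grown in that medium, low-intensity
## polymer impurities confined to 9-13 min / 500-800 m/z, iid ppm-scale m/z
## error, RT jitter, and log-normal intensities clipped to the instrument
## range. Every generated feature carries a provenance label so downstream
## stages can be scored against ground truth.

#' Specification of a synthetic cohort
#'
#' The defaults describe the desk-scale study conditions used throughout the
#' package: 3 suborders x 2 families x 2 genera = 12 genera, 2 species per
#' genus, 3 strains per species (72 data sets, one per strain), 5 cultivation
#' media assigned genus-typically, ~15 produced compound families per strain,
#' 0.6 ppm m/z error, 0.03 min RT jitter, and a background + polymer load
#' giving a mean preprocessing feature reduction of about 20%.
#'
#' @param n_suborders,n_families_per_suborder,n_genera_per_family,n_species_per_genus,n_strains_per_species
#'   Taxonomy tree shape (all >= 1).
#' @param n_media Number of blank cultivation media (default 5).
#' @param n_genus_specific Genus-specific compound families per genus.
#' @param n_species_specific Species-specific compound families per species.
#' @param n_family_shared Families shared by all genera of one taxonomic
#'   family, per taxonomic family.
#' @param n_suborder_shared Families shared by all genera of one suborder,
#'   per suborder.
#' @param n_shared Cosmopolitan compound families shared across suborders.
#' @param genera_per_shared Producing genera per cosmopolitan family (>= 2).
#' @param derivative_prob Probability a family holds a second derivative
#'   compound (same producers, formula + CH2).
#' @param water_loss_prob Probability a compound additionally shows an
#'   in-source water-loss ion `[M+H-H2O]+`.
#' @param detection_prob Probability a produced compound yields features in
#'   a given data set.
#' @param rt_jitter_sd RT jitter standard deviation, minutes.
#' @param mz_error_ppm_sd m/z error standard deviation, ppm.
#' @param envelope_noise_sd Multiplicative log-scale noise on observed
#'   isotope-envelope abundances.
#' @param intensity_log10_mean,intensity_log10_sd Log10-normal intensity
#'   model (median 1e5, sigma 0.5 by default).
#' @param intensity_range Instrument intensity range; intensities are
#'   clipped to it.
#' @param n_background_per_medium Medium-specific background feature centers
#'   per medium.
#' @param n_polymer_features Polymer-impurity features per data set.
#' @param background_jitter_rt_sd,background_jitter_ppm_sd Optional jitter of
#'   background features around their medium centers (0 by default: centers
#'   are identical across data sets sharing a medium).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A validated list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_suborders = 3L,
                        n_families_per_suborder = 2L,
                        n_genera_per_family = 2L,
                        n_species_per_genus = 2L,
                        n_strains_per_species = 3L,
                        n_media = 5L,
                        n_genus_specific = 3L,
                        n_species_specific = 1L,
                        n_family_shared = 3L,
                        n_suborder_shared = 3L,
                        n_shared = 24L,
                        genera_per_shared = 3L,
                        derivative_prob = 0.15,
                        water_loss_prob = 0.15,
                        detection_prob = 0.8,
                        rt_jitter_sd = 0.03,
                        mz_error_ppm_sd = 0.6,
                        envelope_noise_sd = 0.05,
                        intensity_log10_mean = 5,
                        intensity_log10_sd = 0.5,
                        intensity_range = c(2000, 1.25e6),
                        n_background_per_medium = 5L,
                        n_polymer_features = 2L,
                        background_jitter_rt_sd = 0,
                        background_jitter_ppm_sd = 0,
                        seed = 1L) {
  spec <- as.list(environment())
  counts <- c("n_suborders", "n_families_per_suborder",
              "n_genera_per_family", "n_species_per_genus",
              "n_strains_per_species", "n_media")
  for (nm in counts) {
    if (spec[[nm]] < 1L) stop(nm, " must be >= 1", call. = FALSE)
  }
  probs <- c("derivative_prob", "water_loss_prob", "detection_prob")
  for (nm in probs) {
    if (spec[[nm]] < 0 || spec[[nm]] > 1) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (spec$n_shared > 0L && spec$genera_per_shared < 2L) {
    stop("shared compounds need genera_per_shared >= 2", call. = FALSE)
  }
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic taxonomy registry
#'
#' Builds the strain registry as a balanced tree over the rank counts in the
#' spec, and assigns each genus a genus-typical cultivation medium by cycling
#' through the media, so several genera (including genera from different
#' suborders) share a medium -- the confound the media-blank filtering is
#' meant to neutralise.
#'
#' @param spec A [cohort_spec()].
#' @return A taxonomy registry tibble (one row per strain) with `medium_id`.
#' @export
generate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- list()
  g <- 0L
  for (so in seq_len(spec$n_suborders)) {
    for (fa in seq_len(spec$n_families_per_suborder)) {
      for (ge in seq_len(spec$n_genera_per_family)) {
        g <- g + 1L
        genus <- sprintf("Gen%02d", g)
        medium <- sprintf("M%d", (g - 1L) %% spec$n_media + 1L)
        for (sp in seq_len(spec$n_species_per_genus)) {
          species <- sprintf("%s_sp%d", genus, sp)
          for (st in seq_len(spec$n_strains_per_species)) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              strain_id = sprintf("%s_s%02d", species, st),
              species = species, genus = genus,
              family = sprintf("Fam%02d",
                               (so - 1L) * spec$n_families_per_suborder + fa),
              suborder = sprintf("SO%d", so),
              medium_id = medium)
          }
        }
      }
    }
  }
  validate_taxonomy(dplyr::bind_rows(rows))
}

# Sample a CHNOPS element-count vector with monoisotopic mass in [200, 1200].
sample_formula <- function() {
  repeat {
    counts <- c(C = sample(12:55, 1),
                N = sample(0:4, 1),
                O = sample(2:12, 1),
                P = stats::rbinom(1, 1, 0.15),
                S = stats::rbinom(1, 1, 0.10))
    counts["H"] <- round(counts[["C"]] * stats::runif(1, 1.2, 2.1))
    counts <- counts[counts > 0]
    m <- monoisotopic_mass(counts)
    if (m >= 200 && m <= 1200) return(counts)
  }
}

sample_adducts <- function(spec) {
  pool <- c("[M+Na]+", "[M+NH4]+", "[M-H]-")
  n_extra <- sample(0:2, 1)
  adducts <- c("[M+H]+", sample(pool, n_extra))
  if (stats::runif(1) < spec$water_loss_prob) {
    adducts <- c(adducts, "[M+H-H2O]+")
  }
  adducts
}

#' Generate a synthetic compound library with ground truth
#'
#' Plants compound families at five taxonomic scopes: species-specific,
#' genus-specific, shared by the genera of one taxonomic family, shared
#' within one suborder, and cosmopolitan (a random set of >= 2 genera drawn
#' across the cohort). Formulas are sampled from CHNOPS space with masses in
#' 200-1200 Da, reference RTs uniform in 1-20 min, and each compound carries
#' 1-3 adducts (always including `[M+H]+`) plus optionally an in-source
#' water-loss ion.
#'
#' Uses the current RNG state; call within [withr::with_seed()] or via
#' [simulate_cohort()] for reproducibility.
#'
#' @param spec A [cohort_spec()].
#' @param registry Taxonomy registry from [generate_taxonomy()].
#' @return `list(library = <compound library tibble>, truth = <tibble of
#'   compound_name, family_name, scope, producing genera/species,
#'   has_water_loss>)`.
#' @export
generate_compound_library <- function(spec, registry) {
  genera <- unique(registry$genus)
  lib_rows <- list()
  truth_rows <- list()
  add_family <- function(family_name, scope, genera_set, species_set = NA) {
    n_members <- 1L + (stats::runif(1) < spec$derivative_prob)
    base_counts <- sample_formula()
    ref_rt <- stats::runif(1, 1, 20)
    for (k in seq_len(n_members)) {
      counts <- base_counts
      if (k > 1L) {  # homologous derivative: +CH2, slightly later eluting
        counts["C"] <- counts[["C"]] + 1L
        counts["H"] <- counts[["H"]] + 2L
      }
      adducts <- sample_adducts(spec)
      name <- sprintf("%s_c%d", family_name, k)
      lib_rows[[length(lib_rows) + 1L]] <<- tibble::tibble(
        compound_name = name, family_name = family_name,
        formula = format_formula(counts),
        reference_rt = min(20, ref_rt + (k - 1L) * 0.8),
        adducts = list(adducts))
      truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
        compound_name = name, family_name = family_name, scope = scope,
        producing_genera = list(genera_set),
        producing_species = list(species_set),
        has_water_loss = "[M+H-H2O]+" %in% adducts)
    }
  }
  for (g in genera) {
    for (k in seq_len(spec$n_genus_specific)) {
      add_family(sprintf("gs_%s_%d", g, k), "genus_specific", g)
    }
  }
  species_map <- dplyr::distinct(registry[, c("species", "genus")])
  for (i in seq_len(nrow(species_map))) {
    for (k in seq_len(spec$n_species_specific)) {
      add_family(sprintf("ss_%s_%d", species_map$species[i], k),
                 "species_specific", species_map$genus[i],
                 species_map$species[i])
    }
  }
  fam_map <- dplyr::distinct(registry[, c("family", "genus")])
  for (fam in unique(fam_map$family)) {
    gset <- fam_map$genus[fam_map$family == fam]
    for (k in seq_len(spec$n_family_shared)) {
      add_family(sprintf("fs_%s_%d", fam, k), "family_shared", gset)
    }
  }
  so_map <- dplyr::distinct(registry[, c("suborder", "genus")])
  for (so in unique(so_map$suborder)) {
    gset <- so_map$genus[so_map$suborder == so]
    for (k in seq_len(spec$n_suborder_shared)) {
      add_family(sprintf("os_%s_%d", so, k), "suborder_shared", gset)
    }
  }
  if (spec$n_shared > 0L) {
    for (k in seq_len(spec$n_shared)) {
      gset <- sample(genera, min(spec$genera_per_shared, length(genera)))
      add_family(sprintf("cs_%d", k), "shared", gset)
    }
  }
  library <- validate_compound_library(dplyr::bind_rows(lib_rows))
  list(library = library, truth = dplyr::bind_rows(truth_rows))
}

# Medium-specific background feature centers, kept clear of all library
# adduct positions (2x the blank-subtraction window) so background removal
# never collides with planted compounds.
generate_background_centers <- function(spec, library) {
  targets <- adduct_targets(library)
  media <- sprintf("M%d", seq_len(spec$n_media))
  rows <- list(tibble::tibble(medium_id = character(),
                              center_id = character(), mz = numeric(),
                              rt = numeric(), intensity = numeric()))
  for (m in media) {
    got <- 0L
    while (got < spec$n_background_per_medium) {
      mz <- stats::runif(1, 160, 1600)
      rt <- stats::runif(1, 1, 20)
      clash <- any(abs(targets$mz - mz) <= 0.03 & abs(targets$rt - rt) <= 0.2)
      if (clash) next
      got <- got + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        medium_id = m, center_id = sprintf("%s_bg%02d", m, got),
        mz = mz, rt = rt,
        intensity = 10^stats::rnorm(1, 4.5, 0.3))
    }
  }
  dplyr::bind_rows(rows)
}

# All (compound, adduct) target positions of a library.
adduct_targets <- function(library) {
  rows <- lapply(seq_len(nrow(library)), function(i) {
    tibble::tibble(
      compound_name = library$compound_name[i],
      family_name = library$family_name[i],
      adduct = library$adducts[[i]],
      mz = vapply(library$adducts[[i]], function(a)
        adduct_mz(library$neutral_mass[i], a), numeric(1)),
      rt = library$reference_rt[i])
  })
  dplyr::bind_rows(rows)
}

clip <- function(x, range) pmin(pmax(x, range[1]), range[2])

sample_intensity <- function(n, spec) {
  clip(10^stats::rnorm(n, spec$intensity_log10_mean, spec$intensity_log10_sd),
       spec$intensity_range)
}

#' Generate one synthetic data set
#'
#' Emits, for each compound produced by the strain's taxon and surviving the
#' per-compound detection draw, one feature per adduct with ppm-scale m/z
#' error and RT jitter and a noisy theoretical isotope envelope; adds the
#' medium's background feature centers and low-intensity polymer impurities
#' (RT 9-13 min, m/z 500-800, intensity < 20000). Intensities are clipped to
#' the instrument range. Uses the current RNG state (see [simulate_cohort()]).
#'
#' @param strain One row of the taxonomy registry.
#' @param library Compound library tibble.
#' @param truth Ground-truth tibble from [generate_compound_library()].
#' @param spec A [cohort_spec()].
#' @param background_centers Centers from the internal background generator
#'   (shared across all data sets of a medium).
#' @return A feature tibble with provenance columns `provenance`
#'   (`"compound"`, `"background"`, `"polymer"`), `compound_name`, `adduct`.
#' @export
generate_dataset <- function(strain, library, truth, spec,
                             background_centers) {
  produced <- vapply(seq_len(nrow(truth)), function(i) {
    g_ok <- strain$genus %in% truth$producing_genera[[i]]
    sp <- truth$producing_species[[i]]
    g_ok && (all(is.na(sp)) || strain$species %in% sp)
  }, logical(1))
  rows <- list()
  for (i in which(produced)) {
    if (stats::runif(1) > spec$detection_prob) next
    li <- match(truth$compound_name[i], library$compound_name)
    pattern <- theoretical_isotope_pattern(library$counts[[li]], n_peaks = 3L)
    for (a in library$adducts[[li]]) {
      mz_theo <- adduct_mz(library$neutral_mass[li], a)
      mz <- mz_theo * (1 + stats::rnorm(1, 0, spec$mz_error_ppm_sd * 1e-6))
      rt <- clip(library$reference_rt[li] + stats::rnorm(1, 0, spec$rt_jitter_sd),
                 RT_RANGE)
      ab <- pattern$abundance *
        exp(stats::rnorm(nrow(pattern), 0, spec$envelope_noise_sd))
      ab <- ab / max(ab)
      iso <- rep(NA_real_, 3L)
      iso[seq_along(ab)] <- ab
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mz = mz, rt = rt, intensity = sample_intensity(1, spec),
        iso1 = iso[1], iso2 = iso[2], iso3 = iso[3],
        provenance = "compound",
        compound_name = library$compound_name[li], adduct = a)
    }
  }
  bg <- background_centers[background_centers$medium_id == strain$medium_id, ]
  if (nrow(bg) > 0) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      mz = bg$mz * (1 + stats::rnorm(nrow(bg), 0,
                                     spec$background_jitter_ppm_sd * 1e-6)),
      rt = clip(bg$rt + stats::rnorm(nrow(bg), 0,
                                     spec$background_jitter_rt_sd), RT_RANGE),
      intensity = clip(bg$intensity * exp(stats::rnorm(nrow(bg), 0, 0.2)),
                       spec$intensity_range),
      iso1 = NA_real_, iso2 = NA_real_, iso3 = NA_real_,
      provenance = "background", compound_name = NA_character_,
      adduct = NA_character_)
  }
  if (spec$n_polymer_features > 0L) {
    np <- spec$n_polymer_features
    rows[[length(rows) + 1L]] <- tibble::tibble(
      mz = stats::runif(np, 500, 800), rt = stats::runif(np, 9, 13),
      intensity = stats::runif(np, 2000, 19999),
      iso1 = NA_real_, iso2 = NA_real_, iso3 = NA_real_,
      provenance = "polymer", compound_name = NA_character_,
      adduct = NA_character_)
  }
  feats <- dplyr::bind_rows(rows)
  dataset_id <- paste0("D_", strain$strain_id)
  out <- tibble::tibble(
    dataset_id = dataset_id, strain_id = strain$strain_id,
    suborder = strain$suborder, family = strain$family,
    genus = strain$genus, species = strain$species,
    medium_id = strain$medium_id,
    feature_id = sprintf("%s_f%04d", dataset_id, seq_len(nrow(feats))))
  dplyr::bind_cols(out, feats)
}

#' Generate blank-medium data sets
#'
#' One data set per medium holding exactly the medium's background feature
#' centers: no compounds and no jitter.
#'
#' @param spec A [cohort_spec()].
#' @param background_centers Centers shared with [generate_dataset()].
#' @return A feature tibble of blank data sets (taxonomy columns set to
#'   `"blank"`).
#' @export
generate_blank_media <- function(spec, background_centers) {
  rows <- lapply(sprintf("M%d", seq_len(spec$n_media)), function(m) {
    bg <- background_centers[background_centers$medium_id == m, ]
    dataset_id <- paste0("BLANK_", m)
    tibble::tibble(
      dataset_id = dataset_id, strain_id = dataset_id,
      suborder = "blank", family = "blank", genus = "blank",
      species = "blank", medium_id = m,
      feature_id = sprintf("%s_f%03d", dataset_id,
                           seq_len(max(nrow(bg), 0))),
      mz = bg$mz, rt = bg$rt, intensity = bg$intensity,
      iso1 = NA_real_, iso2 = NA_real_, iso3 = NA_real_,
      provenance = "background", compound_name = NA_character_,
      adduct = NA_character_)
  })
  dplyr::bind_rows(rows)
}

#' Simulate a full synthetic cohort
#'
#' Deterministic given `spec$seed`: generates the taxonomy registry, the
#' compound library with ground truth, medium background centers, blank
#' media data sets and one data set per strain.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `"chemotax_cohort"` with elements `spec`,
#'   `registry`, `library`, `truth`, `background_centers`, `blanks`
#'   (feature tibble) and `features` (feature tibble over all strains, with
#'   provenance columns).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    registry <- generate_taxonomy(spec)
    lib <- generate_compound_library(spec, registry)
    centers <- generate_background_centers(spec, lib$library)
    blanks <- generate_blank_media(spec, centers)
    features <- dplyr::bind_rows(lapply(seq_len(nrow(registry)), function(i) {
      generate_dataset(registry[i, ], lib$library, lib$truth, spec, centers)
    }))
  })
  validate_features(features)
  structure(list(spec = spec, registry = registry, library = lib$library,
                 truth = lib$truth, background_centers = centers,
                 blanks = blanks, features = features),
            class = "chemotax_cohort")
}

#' @export
print.chemotax_cohort <- function(x, ...) {
  cat("Synthetic LC-MS cohort:",
      length(unique(x$features$dataset_id)), "data sets,",
      nrow(x$features), "features,",
      nrow(x$library), "library compounds,",
      length(unique(x$registry$genus)), "genera\n")
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Writes `features.tsv`, `blanks.tsv`, `taxonomy.tsv`, `library.tsv` and
#' `ground_truth.tsv` under `dir`.
#'
#' @param cohort A `"chemotax_cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(cohort$features, file.path(dir, "features.tsv"))
  write_feature_table(cohort$blanks, file.path(dir, "blanks.tsv"))
  write_taxonomy(cohort$registry, file.path(dir, "taxonomy.tsv"))
  write_compound_library(cohort$library, file.path(dir, "library.tsv"))
  truth <- cohort$truth
  truth$producing_genera <- vapply(truth$producing_genera, paste,
                                   character(1), collapse = ";")
  truth$producing_species <- vapply(truth$producing_species, function(x)
    paste(stats::na.omit(x), collapse = ";"), character(1))
  write_table_checked(truth, file.path(dir, "ground_truth.tsv"))
  prov <- cohort$features[, c("dataset_id", "feature_id", "provenance",
                              "compound_name", "adduct")]
  write_table_checked(prov, file.path(dir, "provenance.tsv"))
  invisible(dir)
}
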