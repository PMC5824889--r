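rowi_feature <- function(mz, rt, iso = c(1, NA, NA), id = "f1") {
  tibble::tibble(dataset_id = "D1", strain_id = "S1", suborder = "SO1",
                 family = "Fam01", genus = "Gen01", species = "Gen01_sp1",
                 medium_id = "M1", feature_id = id, mz = mz, rt = rt,
                 intensity = 1e5, iso1 = iso[1], iso2 = iso[2],
                 iso3 = iso[3])
}

test_that("tolerance gates behave as strict ppm / inclusive RT", {
  lib <- rowithocin_library()
  mz0 <- adduct_mz(lib$neutral_mass, "[M+H]+")
  pat <- theoretical_isotope_pattern("C35H47O7P", 3)$abundance
  hit <- match_features(rowi_feature(mz0, 16.8, c(pat, NA, NA)[1:3]), lib)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$ppm_error, 0)
  expect_equal(hit$adduct, "[M+H]+")
  expect_false(hit$low_confidence)
  # +6 ppm m/z offset fails the 5 ppm gate
  expect_equal(nrow(match_features(
    rowi_feature(mz0 * (1 + 6e-6), 16.8), lib)), 0L)
  # RT offset of 0.2 min exceeds +/- 0.15
  expect_equal(nrow(match_features(rowi_feature(mz0, 17.0), lib)), 0L)
  # RT gate is inclusive: a deviation of (to within float rounding) 0.15
  # still matches while 0.16 does not
  lib5 <- lib
  lib5$reference_rt <- 2.65
  expect_equal(nrow(match_features(rowi_feature(mz0, 2.5), lib5)), 1L)
  expect_equal(nrow(match_features(rowi_feature(mz0, 2.49), lib5)), 0L)
  # ppm gate: 4.9 ppm passes, 5.1 ppm fails
  expect_equal(nrow(match_features(
    rowi_feature(mz0 * (1 + 4.9e-6), 16.8), lib)), 1L)
  expect_equal(nrow(match_features(
    rowi_feature(mz0 * (1 + 5.1e-6), 16.8), lib)), 0L)
  # missing envelope: isotope gate skipped, match flagged lower-confidence
  noiso <- match_features(rowi_feature(mz0, 16.8, c(NA, NA, NA)), lib)
  expect_equal(nrow(noiso), 1L)
  expect_true(noiso$low_confidence)
  # grossly wrong envelope fails the isotope gate
  expect_equal(nrow(match_features(
    rowi_feature(mz0, 16.8, c(1, 0.9, 0.9)), lib)), 0L)
})

test_that("shrinking any tolerance never adds matches", {
  pr <- default_products()
  feats <- pr$pre$features[pr$pre$features$dataset_id %in%
                             unique(pr$pre$features$dataset_id)[1:4], ]
  lib <- pr$cohort$library
  base <- match_features(feats, lib, match_tolerances(5, 0.15, 50))
  key <- function(m) paste(m$feature_id, m$compound_name, m$adduct)
  for (tol in list(match_tolerances(2, 0.15, 50),
                   match_tolerances(5, 0.05, 50),
                   match_tolerances(5, 0.15, 10))) {
    shrunk <- match_features(feats, lib, tol)
    expect_true(all(key(shrunk) %in% key(base)))
  }
})

test_that("matcher agrees with the brute-force all-pairs oracle", {
  pr <- default_products()
  ds <- unique(pr$pre$features$dataset_id)[1:6]
  feats <- pr$pre$features[pr$pre$features$dataset_id %in% ds, ]
  lib <- pr$cohort$library[1:40, ]
  tol <- match_tolerances()
  got <- match_features(feats, lib, tol)
  want <- match_oracle(feats, lib, tol)
  key <- function(m) sort(paste(m$feature_id, m$compound_name, m$adduct))
  expect_equal(key(got), key(want))
})

test_that("family presence collapses compounds and keeps empty data sets", {
  lib <- validate_compound_library(tibble::tibble(
    compound_name = c("a1", "a2", "b1"),
    family_name = c("famA", "famA", "famB"),
    formula = c("C20H30O5", "C21H32O5", "C15H20N2O3"),
    reference_rt = c(5, 5.5, 9),
    adducts = list("[M+H]+", "[M+H]+", "[M+H]+")))
  feats <- dplyr::bind_rows(
    rowi_feature(adduct_mz(lib$neutral_mass[1], "[M+H]+"), 5, id = "f1"),
    rowi_feature(adduct_mz(lib$neutral_mass[2], "[M+H]+"), 5.5, id = "f2"))
  matches <- match_features(feats, lib)
  m <- family_presence_matrix(matches, lib, dataset_ids = c("D1", "D2"))
  # two compounds of one family count once; unmatched family stays 0;
  # the matchless data set is an all-zero column
  expect_equal(unclass(m)["famA", "D1"], 1)
  expect_equal(unclass(m)["famB", "D1"], 0)
  expect_equal(sum(unclass(m)[, "D2"]), 0)
})

test_that("planted knowns are recovered with no decoy false positives", {
  pr <- default_products()
  feats <- pr$pre$features
  lib <- pr$cohort$library
  matches <- match_features(feats, lib)
  # sensitivity at the (family, data set) level against surviving truth
  truth_pairs <- unique(paste(
    lib$family_name[match(feats$compound_name, lib$compound_name)][
      feats$provenance == "compound"],
    feats$dataset_id[feats$provenance == "compound"]))
  got_pairs <- unique(paste(matches$family_name, matches$dataset_id))
  sensitivity <- mean(truth_pairs %in% got_pairs)
  expect_gte(sensitivity, 0.95)
  # decoys displaced far beyond 10x every tolerance never match
  decoys <- lib
  decoys$compound_name <- paste0("decoy_", decoys$compound_name)
  decoys$reference_rt <- pmin(20.4, decoys$reference_rt + 1.7)
  decoys$neutral_mass <- decoys$neutral_mass * (1 + 500e-6)
  expect_equal(nrow(match_features(feats, decoys)), 0L)
})

test_that("neutral-loss linking annotates in-source fragments", {
  expect_equal(link_neutral_loss(515.350, 497.339), "H2O")
  expect_true(is.na(link_neutral_loss(515.350, 400.000)))
  # predicted water-loss fragment of the [M+H]+ ion
  frag <- adduct_mz(monoisotopic_mass("C35H47O7P"), "[M+H-H2O]+")
  expect_lt(abs(frag - 593.3026), 1e-4)
  expect_equal(
    link_neutral_loss(adduct_mz(monoisotopic_mass("C35H47O7P"), "[M+H]+"),
                      frag), "H2O")
  # extensible loss table
  losses <- rbind(neutral_loss_table(),
                  tibble::tibble(name = "C2H4", mass = 28.0313))
  expect_equal(link_neutral_loss(500, 500 - 28.0313, losses), "C2H4")
})
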