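test_that("taxonomy generation is a deterministic balanced tree", {
  single <- generate_taxonomy(cohort_spec(
    n_suborders = 1, n_families_per_suborder = 1, n_genera_per_family = 1,
    n_species_per_genus = 1, n_strains_per_species = 1))
  expect_equal(nrow(single), 1L)
  spec <- cohort_spec()
  reg <- generate_taxonomy(spec)
  expect_equal(nrow(reg), 3 * 2 * 2 * 2 * 3)
  expect_equal(length(unique(reg$genus)), 12L)
  expect_equal(length(unique(reg$suborder)), 3L)
  expect_identical(generate_taxonomy(spec), generate_taxonomy(spec))
  # several genera share a medium, including across suborders
  med <- unique(reg[, c("genus", "suborder", "medium_id")])
  shared <- split(med, med$medium_id)
  expect_true(any(vapply(shared, function(x)
    length(unique(x$suborder)) > 1, logical(1))))
})

test_that("compound library plants the intended taxonomic scopes", {
  co <- default_cohort()
  spec <- co$spec
  gs <- co$truth[co$truth$scope == "genus_specific", ]
  # every genus-specific family maps to exactly one genus
  expect_true(all(vapply(gs$producing_genera, length, integer(1)) == 1L))
  expect_equal(length(unique(gs$family_name)),
               12L * spec$n_genus_specific)
  shared <- co$truth[co$truth$scope == "shared", ]
  expect_true(all(vapply(shared$producing_genera, length,
                         integer(1)) >= 2L))
  # masses within the sampled window, reference RTs within 1-20 min
  expect_true(all(co$library$neutral_mass >= 200 &
                    co$library$neutral_mass <= 1200))
  expect_true(all(co$library$reference_rt >= 1 &
                    co$library$reference_rt <= 20))
  # ground truth flags water-loss (in-source fragment) compounds
  expect_true(any(co$truth$has_water_loss))
  wl <- co$library[co$library$compound_name %in%
                     co$truth$compound_name[co$truth$has_water_loss], ]
  expect_true(all(vapply(wl$adducts, function(a)
    "[M+H-H2O]+" %in% a, logical(1))))
})

test_that("generated features are internally consistent with the library", {
  co <- default_cohort()
  cf <- co$features[co$features$provenance == "compound", ]
  li <- match(cf$compound_name, co$library$compound_name)
  mz_theo <- mapply(function(i, a) adduct_mz(co$library$neutral_mass[i], a),
                    li, cf$adduct)
  # observed m/z within a few ppm of the exact adduct m/z (0.6 ppm sd)
  expect_true(all(abs(cf$mz - mz_theo) / mz_theo * 1e6 < 6))
  # a zero-noise cohort reproduces adduct m/z exactly
  quiet <- simulate_cohort(cohort_spec(
    n_suborders = 1, n_families_per_suborder = 1, n_genera_per_family = 2,
    n_strains_per_species = 1, mz_error_ppm_sd = 0, rt_jitter_sd = 0,
    n_background_per_medium = 0, n_polymer_features = 0, seed = 8))
  qf <- quiet$features
  qi <- match(qf$compound_name, quiet$library$compound_name)
  qmz <- mapply(function(i, a) adduct_mz(quiet$library$neutral_mass[i], a),
                qi, qf$adduct)
  expect_equal(qf$mz, unname(qmz), tolerance = 1e-12)
  # genus-specific compounds appear only in data sets of their genus
  gs <- co$truth[co$truth$scope == "genus_specific", ]
  cf_gs <- cf[cf$compound_name %in% gs$compound_name, ]
  planted <- unlist(gs$producing_genera[
    match(cf_gs$compound_name, gs$compound_name)])
  expect_true(all(cf_gs$genus == planted))
})

test_that("every feature has exactly one provenance label and counts add up", {
  co <- default_cohort()
  expect_true(all(co$features$provenance %in%
                    c("compound", "background", "polymer")))
  per_ds <- table(co$features$dataset_id)
  parts <- table(co$features$dataset_id, co$features$provenance)
  expect_equal(as.integer(per_ds), as.integer(rowSums(parts)))
  # intensity clipping to the instrument range
  expect_true(all(co$features$intensity >= 2000 &
                    co$features$intensity <= 1.25e6))
  # polymer features confined to their window
  poly <- co$features[co$features$provenance == "polymer", ]
  expect_true(all(poly$rt >= 9 & poly$rt <= 13 &
                    poly$mz >= 500 & poly$mz <= 800 &
                    poly$intensity < 20000))
})

test_that("blank media hold exactly the background centers", {
  co <- default_cohort()
  expect_equal(length(unique(co$blanks$dataset_id)), co$spec$n_media)
  for (m in unique(co$blanks$medium_id)) {
    b <- co$blanks[co$blanks$medium_id == m, ]
    centers <- co$background_centers[
      co$background_centers$medium_id == m, ]
    expect_equal(sort(b$mz), sort(centers$mz))
    expect_equal(sort(b$rt), sort(centers$rt))
  }
  # background features in strain data sets sit exactly on the centers
  bg <- co$features[co$features$provenance == "background", ]
  expect_true(all(bg$mz %in% co$background_centers$mz))
})

test_that("identical seeds give byte-identical output files", {
  spec <- cohort_spec(seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(spec), d1)
  write_cohort(simulate_cohort(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
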