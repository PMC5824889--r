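tax_row <- function(species, genus, family, suborder) {
  tibble::tibble(species = species, genus = genus, family = family,
                 suborder = suborder)
}

test_that("cosine distance has the documented values and conventions", {
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosine_distance(c(0, 0), c(1, 0)), 1)   # zero vs non-zero
  expect_equal(cosine_distance(c(0, 0), c(0, 0)), 0)   # zero vs zero
  expect_error(cosine_distance(c(1, 0), c(1, 0, 1)), "length")
  set.seed(4)
  for (k in 1:10) {
    a <- rbinom(30, 1, 0.4); b <- rbinom(30, 1, 0.4)
    expect_equal(cosine_distance(a, b), cosine_oracle(a, b))
    expect_equal(cosine_distance(a, b), cosine_distance(b, a))
  }
})

test_that("strain pairs are classified into the four contrast series", {
  a <- tax_row("g1_s1", "G1", "F1", "SO1")
  expect_equal(classify_pair(a, tax_row("g1_s1", "G1", "F1", "SO1")),
               "within_species")
  expect_equal(classify_pair(a, tax_row("g1_s2", "G1", "F1", "SO1")),
               "between_species_within_genus")
  expect_equal(classify_pair(a, tax_row("g2_s1", "G2", "F1", "SO1")),
               "between_genera_within_family")
  expect_equal(classify_pair(a, tax_row("g9_s1", "G9", "F9", "SO2")),
               "between_suborders")
  # same suborder, different family: none of the four series
  expect_true(is.na(classify_pair(a, tax_row("g5_s1", "G5", "F2", "SO1"))))
  # unclassified species never count as within-species
  u1 <- tax_row("unclassified", "G1", "F1", "SO1")
  u2 <- tax_row("unclassified", "G1", "F1", "SO1")
  expect_false(identical(classify_pair(u1, u2), "within_species"))
})

test_that("pair counts per contrast match the combinatorial oracle", {
  pr <- default_products()
  rsd <- rank_stratified_distances(pr$occ, pr$registry)
  reg <- pr$registry
  ch2 <- function(n) n * (n - 1) / 2
  n_sp <- table(reg$species)
  n_g <- table(reg$genus)
  n_f <- table(reg$family)
  n_so <- table(reg$suborder)
  want <- c(
    within_species = sum(ch2(n_sp)),
    between_species_within_genus = sum(ch2(n_g)) - sum(ch2(n_sp)),
    between_genera_within_family = sum(ch2(n_f)) - sum(ch2(n_g)),
    between_suborders = ch2(nrow(reg)) - sum(ch2(n_so)))
  got <- table(rsd$distances$label)
  expect_equal(as.integer(got[names(want)]), unname(as.integer(want)))
  # every unordered pair appears once, classified or not
  expect_equal(nrow(rsd$distances), ch2(nrow(reg)))
  # histogram counts add up to pair counts
  hist_tot <- tapply(rsd$histogram$count, rsd$histogram$label, sum)
  expect_equal(as.integer(hist_tot[names(want)]),
               unname(as.integer(want)))
  expect_true(all(rsd$distances$distance >= 0 &
                    rsd$distances$distance <= 1))
})

test_that("profile distance grows with taxonomic rank on a planted cohort", {
  pr <- default_products()
  rsd <- rank_stratified_distances(pr$occ, pr$registry)
  m <- rsd$summary$mean[match(
    c("within_species", "between_species_within_genus",
      "between_genera_within_family", "between_suborders"),
    rsd$summary$label)]
  expect_true(all(diff(m) > 0))
  # removing genus/species-specific rows shrinks the between-within gap
  truth <- pr$cohort$truth
  spec_names <- truth$compound_name[truth$scope %in%
                                      c("genus_specific",
                                        "species_specific")]
  ann <- annotate_buckets(pr$bk$buckets, pr$cohort$library)
  drop <- ann$bucket_id[!is.na(ann$compound_name) &
                          ann$compound_name %in% spec_names]
  pruned <- occurrence_matrix(
    unclass(pr$occ)[setdiff(rownames(pr$occ), drop), , drop = FALSE],
    "binary")
  rsd2 <- rank_stratified_distances(pruned, pr$registry)
  gap <- function(x) {
    x$summary$mean[x$summary$label == "between_genera_within_family"] -
      x$summary$mean[x$summary$label == "within_species"]
  }
  expect_lt(gap(rsd2), gap(rsd))
})

test_that("paired t-test uses per-strain means with the closed-form t", {
  # construct probe strains with exactly one pair in each contrast so the
  # per-strain differences are known: mean 1, sd 1, n = 100 -> t = 10
  n <- 100
  z <- as.numeric(scale(stats::rnorm(n)))   # exact mean 0, sd 1
  diffs <- 1 + z
  distances <- dplyr::bind_rows(
    tibble::tibble(dataset_a = sprintf("P%03d", 1:n),
                   dataset_b = sprintf("A%03d", 1:n),
                   strain_a = sprintf("P%03d", 1:n),
                   strain_b = sprintf("A%03d", 1:n),
                   label = "within_species", distance = diffs),
    tibble::tibble(dataset_a = sprintf("P%03d", 1:n),
                   dataset_b = sprintf("B%03d", 1:n),
                   strain_a = sprintf("P%03d", 1:n),
                   strain_b = sprintf("B%03d", 1:n),
                   label = "between_genera_within_family", distance = 0))
  res <- paired_profile_test(distances)
  expect_equal(res$t, 10)
  expect_equal(res$df, 99)
  expect_equal(res$n_pairs, 100L)
  expect_equal(res$conf_level, 0.99)
  expect_true(res$conf_low < res$estimate & res$estimate < res$conf_high)
  # identical means: t = 0, p = 1
  same <- distances
  same$distance[same$label == "between_genera_within_family"] <- diffs
  res0 <- paired_profile_test(same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p_value, 1)
  # degenerate: constant non-zero difference
  shifted <- distances
  shifted$distance[shifted$label == "within_species"] <- 1
  shifted$distance[shifted$label == "between_genera_within_family"] <- 0
  expect_error(paired_profile_test(shifted), "degenerate")
  expect_error(paired_profile_test(distances[1:2, ]), "fewer than 2")
})
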