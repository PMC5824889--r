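avail_registry <- function(avail) {
  dplyr::bind_rows(lapply(names(avail), function(g) {
    tibble::tibble(dataset_id = sprintf("%s_%03d", g, seq_len(avail[[g]])),
                   genus = g)
  }))
}

test_that("genus-balanced subsampling honours cap and minimum", {
  expect_length(subsample_datasets(avail_registry(c(A = 5, B = 8))), 0L)
  expect_length(subsample_datasets(avail_registry(c(Hyalangium = 22))), 22L)
  reg <- avail_registry(c(A = 30, B = 120, C = 10))
  sel <- subsample_datasets(reg, seed = 3)
  tab <- table(sub("_.*", "", sel))
  expect_equal(as.integer(tab[c("A", "B")]), c(30L, 50L))
  expect_false("C" %in% names(tab))
  # seeded draws are reproducible; selection is without replacement
  expect_identical(sel, subsample_datasets(reg, seed = 3))
  expect_equal(anyDuplicated(sel), 0L)
})

test_that("collapsing counts occurrences per taxon and conserves totals", {
  m <- matrix(c(1, 0, 1, 1, 0, 1, 1, 0), nrow = 2,
              dimnames = list(c("b1", "b2"), paste0("D", 1:4)))
  reg <- tibble::tibble(
    dataset_id = paste0("D", 1:4), strain_id = paste0("S", 1:4),
    species = c("g1_s1", "g1_s1", "g1_s2", "g2_s1"),
    genus = c("G1", "G1", "G1", "G2"),
    family = c("F1", "F1", "F1", "F1"),
    suborder = "SO1", medium_id = "M1")
  om <- occurrence_matrix(m, "binary")
  gen <- collapse_matrix(om, reg, "genus")
  expect_equal(unclass(gen)["b1", "G1"], 2)   # bucket in 2 of 3 G1 data sets
  expect_equal(unclass(gen)["b1", "G2"], 1)
  expect_equal(attr(gen, "n_datasets")[["G1"]], 3L)
  # conservation: taxon counts sum to binary row sums
  expect_equal(unname(rowSums(unclass(gen))), unname(rowSums(m)))
  # collapsing to genus then regrouping genera by family equals
  # collapsing to family directly
  fam <- collapse_matrix(om, reg, "family")
  fam_from_gen <- t(rowsum(t(unclass(gen)),
                           group = c(G1 = "F1", G2 = "F1")[colnames(gen)]))
  expect_equal(unclass(fam)[, "F1"], fam_from_gen[, "F1"])
  expect_error(collapse_matrix(om, reg, "kingdom"))
})

test_that("specificity classes honour the strict >0.95 / =1 thresholds", {
  m <- rbind(only_one = c(7, 0, 0),
             exactly_95 = c(19, 1, 0),
             ninety_six = c(96, 3, 1),
             spread = c(5, 5, 5),
             empty = c(0, 0, 0))
  colnames(m) <- c("G1", "G2", "G3")
  om <- occurrence_matrix(m, "count")
  expect_warning(sp <- score_specificity(om), "zero detections")
  expect_equal(sp$class[sp$row_id == "only_one"], "unique")
  expect_equal(sp$class[sp$row_id == "exactly_95"], "nonspecific")
  expect_equal(sp$class[sp$row_id == "ninety_six"], "highly_specific")
  expect_equal(sp$class[sp$row_id == "spread"], "nonspecific")
  expect_false("empty" %in% sp$row_id)
  expect_equal(sp$fraction[sp$row_id == "ninety_six"], 0.96)
  # invariance to duplicating all data sets of every genus equally
  om2 <- occurrence_matrix(m[1:4, ] * 3, "count")
  expect_equal(score_specificity(om2)$class, sp$class)
})

test_that("overlap counts partition the detected rows", {
  m <- rbind(a_only = c(1, 0), b_only = c(0, 1), both = c(1, 1))
  colnames(m) <- c("D1", "D2")
  reg <- tibble::tibble(
    dataset_id = c("D1", "D2"), strain_id = c("S1", "S2"),
    species = c("s1", "s2"), genus = c("G1", "G2"),
    family = c("F1", "F2"), suborder = c("SO1", "SO2"), medium_id = "M1")
  ov <- rank_overlap_counts(occurrence_matrix(m, "binary"), reg, "suborder")
  expect_equal(ov$subset_counts[["SO1"]], 1L)
  expect_equal(ov$subset_counts[["SO2"]], 1L)
  expect_equal(ov$subset_counts[["SO1&SO2"]], 1L)
  expect_equal(sum(ov$subset_counts), ov$n_detected)
  expect_equal(ov$exclusive, c(SO1 = 1L, SO2 = 1L))
  # permutation invariance in column order
  ov2 <- rank_overlap_counts(
    occurrence_matrix(m[, 2:1], "binary"), reg, "suborder")
  expect_equal(ov2$subset_counts[names(ov$subset_counts)],
               ov$subset_counts)
})

test_that("genus-exclusive buckets cover the planted specific compounds", {
  pr <- default_products()
  ov <- rank_overlap_counts(pr$occ, pr$registry, "genus")
  truth <- pr$cohort$truth
  n_planted_unique <- sum(truth$scope %in%
                            c("genus_specific", "species_specific") &
                            vapply(truth$producing_genera, length,
                                   integer(1)) == 1)
  # each genus-specific compound contributes >= 1 exclusive bucket
  expect_gte(sum(ov$exclusive), n_planted_unique * 0.9)
})

test_that("bucket statistics follow the Tukey convention", {
  assignment <- tibble::tibble(
    dataset_id = rep("D1", 5), feature_id = paste0("f", 1:5),
    bucket_id = "B1")
  feats <- tibble::tibble(
    dataset_id = "D1", feature_id = paste0("f", 1:5),
    mz = 400, rt = 5, intensity = c(1e4, 1e4, 1e4, 1e4, 1e4))
  reg <- tibble::tibble(dataset_id = "D1", strain_id = "S1",
                        species = "s", genus = "G1", family = "F1",
                        suborder = "SO1", medium_id = "M1")
  st <- bucket_stats("B1", assignment, feats, reg)
  expect_equal(st$iqr, 0)
  expect_length(st$outliers[[1]], 0L)
  # {1..100, 1000}: the single extreme value is flagged
  assignment2 <- tibble::tibble(
    dataset_id = "D1", feature_id = paste0("g", 1:101), bucket_id = "B2")
  feats2 <- tibble::tibble(
    dataset_id = "D1", feature_id = paste0("g", 1:101),
    mz = 400, rt = 5, intensity = c(1:100 * 1000, 1e6))
  st2 <- bucket_stats("B2", assignment2, feats2, reg)
  expect_equal(st2$outliers[[1]], 1e6)
  # type-7 quartiles of {1,2,3,4}
  assignment3 <- tibble::tibble(
    dataset_id = "D1", feature_id = paste0("h", 1:4), bucket_id = "B3")
  feats3 <- tibble::tibble(
    dataset_id = "D1", feature_id = paste0("h", 1:4),
    mz = 400, rt = 5, intensity = c(2001, 3000, 4000, 5000))
  st3 <- bucket_stats("B3", assignment3, feats3, reg)
  expect_equal(st3$q1, unname(quantile(c(2001, 3000, 4000, 5000), 0.25)))
  expect_equal(st3$median, 3500)
})
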