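make_features <- function(n = 4, dataset_id = "D1") {
  tibble::tibble(
    dataset_id = dataset_id, strain_id = "S1", suborder = "SO1",
    family = "Fam01", genus = "Gen01", species = "Gen01_sp1",
    medium_id = "M1",
    feature_id = sprintf("f%02d", seq_len(n)),
    mz = seq(300, 300 + n - 1), rt = seq(2, by = 0.5, length.out = n),
    intensity = rep(1e5, n),
    iso1 = 1, iso2 = 0.3, iso3 = NA_real_)
}

test_that("feature tables round-trip through TSV and CSV", {
  f <- make_features(5)
  for (ext in c("tsv", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_feature_table(f, path)
    got <- read_feature_table(path)
    expect_equal(got$mz, f$mz)
    expect_equal(got$feature_id, f$feature_id)
    expect_equal(got$iso2, f$iso2)
  }
})

test_that("feature validation rejects range and uniqueness violations", {
  f <- make_features()
  f$rt[2] <- 25
  expect_error(validate_features(f), "RT outside.*rows: 2")
  f <- make_features()
  f$mz[3] <- 3000
  expect_error(validate_features(f), "m/z outside")
  f <- make_features()
  f$intensity[1] <- 0
  expect_error(validate_features(f), "intensity")
  f <- make_features()
  f$feature_id[2] <- f$feature_id[1]
  expect_error(validate_features(f), "duplicate feature_id")
  expect_error(validate_features(make_features()[, -8]), "missing columns")
})

test_that("truncated files are rejected via the row-count footer", {
  f <- make_features(6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(f, path)
  lines <- readLines(path)
  # drop a data row but keep the footer
  writeLines(lines[-4], path)
  expect_error(read_feature_table(path), "truncated")
})

test_that("taxonomy validation enforces functional rank mappings", {
  tax <- tibble::tibble(
    strain_id = c("s1", "s2", "s3"),
    species = c("g1_sp1", "g1_sp2", "unclassified"),
    genus = c("Gen01", "Gen01", "Gen02"),
    family = c("Fam01", "Fam01", "Fam02"),
    suborder = c("SO1", "SO1", "SO1"))
  expect_silent(validate_taxonomy(tax))
  bad <- tax
  bad$family[2] <- "Fam09"   # Gen01 now maps to two families
  expect_error(validate_taxonomy(bad), "genus -> family.*s1")
  bad <- tax
  bad$strain_id[2] <- "s1"
  expect_error(validate_taxonomy(bad), "duplicate strain_id")
})

test_that("compound libraries parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(
    c("compound_name\tfamily_name\tformula\treference_rt\tadducts",
      "rowithocin A\trowithocins\tC35H47O7P\t16.8\t[M+H]+;[M−H]−"),
    collapse = "\n"), path)
  lib <- read_compound_library(path)
  expect_equal(length(lib$adducts[[1]]), 2L)
  expect_equal(lib$adducts[[1]], c("[M+H]+", "[M-H]-"))
  expect_equal(round(lib$neutral_mass, 4), 610.3059)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_compound_library(lib, out)
  expect_equal(read_compound_library(out)$adducts, lib$adducts)

  expect_error(validate_compound_library(tibble::tibble(
    compound_name = "x", family_name = "f", formula = "C6H6",
    reference_rt = 5, adducts = list(character(0)))), "empty adduct")
  expect_error(validate_compound_library(tibble::tibble(
    compound_name = c("x", "x"), family_name = "f", formula = "C6H6",
    reference_rt = 5, adducts = list("[M+H]+", "[M+H]+"))),
    "duplicate compound_name")
  expect_error(validate_compound_library(tibble::tibble(
    compound_name = "x", family_name = "f", formula = "C6H6",
    reference_rt = 5, adducts = list("[M+Zz]+"))), "unknown adduct")
})

test_that("occurrence matrices round-trip in dense and sparse dialects", {
  m <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("b1", "b2"), c("d1", "d2")))
  om <- occurrence_matrix(m, values = "binary", rank = "genus")
  dense <- withr::local_tempfile(fileext = ".tsv")
  sparse <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(om, dense, format = "dense")
  write_matrix(om, sparse, format = "sparse")
  got_d <- read_matrix(dense)
  got_s <- read_matrix(sparse)
  expect_equal(unclass(got_d)[, ], unclass(om)[, ])
  expect_equal(unclass(got_s)[, ], unclass(om)[, ])
  expect_equal(attr(got_d, "values"), "binary")
  expect_equal(attr(got_d, "rank"), "genus")

  # sparse keeps empty rows/columns
  m2 <- matrix(0, 3, 2, dimnames = list(paste0("b", 1:3), c("d1", "d2")))
  m2[1, 1] <- 2
  om2 <- occurrence_matrix(m2, values = "count")
  write_matrix(om2, sparse, format = "sparse")
  expect_equal(dim(read_matrix(sparse)), c(3L, 2L))

  # empty matrix: header-only file is valid
  m0 <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("d1", "d2")))
  om0 <- occurrence_matrix(m0, values = "binary")
  write_matrix(om0, sparse, format = "sparse")
  expect_equal(dim(read_matrix(sparse)), c(0L, 2L))
})

test_that("a larger synthetic matrix is identical through both dialects", {
  set.seed(9)
  m <- matrix(rbinom(30 * 8, 1, 0.3), 30, 8,
              dimnames = list(sprintf("b%02d", 1:30), sprintf("d%d", 1:8)))
  om <- occurrence_matrix(m, values = "binary")
  d <- withr::local_tempfile(fileext = ".tsv")
  s <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(om, d, "dense")
  write_matrix(om, s, "sparse")
  expect_equal(unclass(read_matrix(d))[, ], unclass(read_matrix(s))[, ])
})
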