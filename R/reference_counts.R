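## Published reference counts from the large myxobacterial strain-collection
## survey (~2300 LC-MS data sets), bundled as inputs for worked examples:
## per-genus data set availability and the Myxococcus species breakdown.

#' Per-genus LC-MS data set availability of the myxobacterial survey
#'
#' The number of data sets available per genus in the published survey of
#' the order Myxococcales (genera represented by at least 5 strains).
#' Applying the genus-balanced subsampling rule (cap 50, minimum 20) to
#' these availabilities selects the 515 data sets from 12 genera used in
#' the unknowns analysis.
#'
#' @return Named integer vector of data set counts per genus.
#' @examples
#' sum(pmin(myxococcales_genus_availability()[
#'   myxococcales_genus_availability() >= 20], 50)) # 515
#' @export
myxococcales_genus_availability <- function() {
  c(Aetherobacter = 5L, Archangium = 26L, Chondromyces = 50L,
    Corallococcus = 249L, Cystobacter = 242L, Hyalangium = 22L,
    Jahnella = 8L, Melittangium = 44L, Myxococcus = 799L,
    Nannocystis = 146L, Polyangium = 112L, Pyxidicoccus = 23L,
    Sorangium = 499L, Stigmatella = 77L)
}

#' Myxococcus data set counts per species
#'
#' Species breakdown of the 790 Myxococcus data sets used for the
#' sub-genus clustering analysis (including unclassified strains).
#'
#' @return Named integer vector of data set counts per species.
#' @export
myxococcus_species_counts <- function() {
  c(M_virescens = 189L, M_xanthus = 154L, M_stipitatus = 76L,
    M_fulvus = 256L, unclassified = 115L)
}

#' Expand per-taxon availability counts into a dataset registry
#'
#' Convenience for feeding printed availability tables into
#' [subsample_datasets()]: one synthetic `dataset_id` row per available
#' data set.
#'
#' @param availability Named integer vector (names are genera).
#' @return A tibble with columns `dataset_id` and `genus`.
#' @export
availability_registry <- function(availability) {
  dplyr::bind_rows(lapply(names(availability), function(g) {
    tibble::tibble(
      dataset_id = sprintf("%s_%04d", g, seq_len(availability[[g]])),
      genus = g)
  }))
}
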