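Package: chemotax
Title: Chemotaxonomic Analysis of Untargeted LC-MS Metabolite Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chemotaxonomic analysis of untargeted LC-MS feature
    lists from bacterial strain extracts. Implements de-replication of known
    compounds by accurate mass, retention time and isotope-pattern matching;
    removal of polymer-impurity and cultivation-medium background features;
    merging of features across strains into rectangular m/z-retention-time
    buckets; taxon-resolved occurrence matrices with genus-specificity
    scoring and rank-level overlap counts; UPGMA clustering with bootstrap
    and approximately-unbiased clade support; and rank-stratified comparison
    of binary metabolite profiles using the bitvector cosine distance with
    paired t-tests. A synthetic-cohort generator with full feature-level
    ground truth replaces proprietary instrument front ends so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
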