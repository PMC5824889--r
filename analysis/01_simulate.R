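#!/usr/bin/env Rscript
# Stage 1: simulate a taxonomically structured LC-MS cohort.
#
# Generates the desk-scale study cohort: 12 genera in 3 suborders, 2 species
# per genus, 3 strains per species (72 data sets), 5 cultivation media,
# compound families planted at species/genus/family/suborder/cosmopolitan
# scope, plus medium background and polymer impurities -- with feature-level
# ground truth. All downstream stages read the plain-text files written here.

library(chemotax)

seed <- 1L
out <- "results/cohort"

cohort <- simulate_cohort(cohort_spec(seed = seed))
write_cohort(cohort, out)

cat("Simulated cohort (seed ", seed, "):\n", sep = "")
print(cohort)
cat("feature provenance:\n")
print(table(cohort$features$provenance))
cat("compound family scopes:\n")
print(table(cohort$truth$scope))
cat("written to ", out, "\n", sep = "")
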