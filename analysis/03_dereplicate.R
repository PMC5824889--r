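#!/usr/bin/env Rscript
# Stage 3: de-replication of known compounds.
#
# Matches filtered features against the reference library at the standard
# gates (< 5 ppm, +/- 0.15 min, isotope fit < 50) using each compound's
# individually observed adduct types, collapses matches to compound-family
# presence, and links in-source water-loss fragments to their parent ions.

library(chemotax)

features <- read_feature_table("results/filtered.tsv")
library_tbl <- read_compound_library("results/cohort/library.tsv")

matches <- match_features(features, library_tbl)
write.table(matches, "results/matches.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
presence <- family_presence_matrix(matches, library_tbl,
                                   unique(features$dataset_id))
write_matrix(presence, "results/family_presence.tsv", format = "sparse")

cat(sprintf("%d feature matches; %d of %d families detected somewhere\n",
            nrow(matches), sum(rowSums(presence) > 0), nrow(presence)))

# in-source fragments: water-loss ions matched back to their [M+H]+ parent
wl <- matches[matches$adduct == "[M+H-H2O]+", ]
parents <- matches[matches$adduct == "[M+H]+", ]
linked <- 0L
for (i in seq_len(nrow(wl))) {
  p <- parents[parents$dataset_id == wl$dataset_id[i] &
                 parents$compound_name == wl$compound_name[i], ]
  if (nrow(p) == 0) next
  mz_p <- adduct_mz(
    library_tbl$neutral_mass[match(wl$compound_name[i],
                                   library_tbl$compound_name)], "[M+H]+")
  mz_f <- mz_p - monoisotopic_mass("H2O")
  if (identical(link_neutral_loss(mz_p, mz_f), "H2O")) linked <- linked + 1L
}
cat(sprintf("water-loss fragment ions linked to a parent: %d of %d\n",
            linked, nrow(wl)))
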