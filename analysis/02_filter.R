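#!/usr/bin/env Rscript
# Stage 2: background filtering.
#
# Removes polymer impurities (9-13 min, low intensity) and cultivation-medium
# background features (0.2 min x 0.03 m/z windows around blank features),
# and checks the removals against the simulation's provenance labels.

library(chemotax)

features <- read_feature_table("results/cohort/features.tsv")
blanks <- read_feature_table("results/cohort/blanks.tsv")
provenance <- read.delim("results/cohort/provenance.tsv",
                         comment.char = "#")

pre <- preprocess_cohort(features, blanks)
write_feature_table(pre$features, "results/filtered.tsv")
write.table(pre$reports, "results/filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("filtered %d -> %d features; mean fraction removed %.3f\n",
            nrow(features), nrow(pre$features),
            mean(pre$reports$fraction_removed)))

key <- function(d) paste(d$dataset_id, d$feature_id)
kept_prov <- provenance$provenance[match(key(pre$features), key(provenance))]
cat(sprintf("background/polymer features surviving the filter: %d\n",
            sum(kept_prov %in% c("background", "polymer"))))
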