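#!/usr/bin/env Rscript
# Stage 4: bucketing.
#
# Merges the filtered features of all data sets into rectangular 0.2 min x
# 0.03 m/z buckets (greedy centroid procedure), annotates buckets matching
# library compounds as known, and builds the binary bucket x data set
# occurrence matrix that all taxon-level analyses start from.

library(chemotax)

features <- read_feature_table("results/filtered.tsv")
library_tbl <- read_compound_library("results/cohort/library.tsv")

bk <- bucket_features(features)
buckets <- annotate_buckets(bk$buckets, library_tbl)
write.table(buckets, "results/buckets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
occ <- build_occurrence_matrix(bk$assignment, unique(features$dataset_id))
write_matrix(occ, "results/occurrence.tsv", format = "sparse")

cat(sprintf("%d features merged into %d buckets (%.1fx compression)\n",
            nrow(features), nrow(buckets), nrow(features) / nrow(buckets)))
cat(sprintf("known buckets: %d; unknown buckets: %d\n",
            sum(buckets$known), sum(!buckets$known)))
cat(sprintf("occurrence matrix: %d buckets x %d data sets, fill %.3f\n",
            nrow(occ), ncol(occ), mean(unclass(occ))))
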