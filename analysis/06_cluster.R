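#!/usr/bin/env Rscript
# Stage 6: UPGMA clustering with bootstrap support.
#
# Clusters the genus-level profiles by bitvector cosine distance under
# UPGMA, attaches bootstrap (BP) and approximately-unbiased (AU) clade
# supports from row resampling, and exports the dendrogram as Newick.
# The planted taxonomy predicts that genera of one suborder cluster
# together, and that genera sharing only a cultivation medium do not.

library(chemotax)

collapsed <- read_matrix("results/collapsed_genus.tsv")

bs <- bootstrap_support(collapsed, n_boot = 500, method = "au", seed = 1)
write_newick(bs, "results/dendrogram_genus.nwk")
write.table(bs$support, "results/clade_support.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

d <- profile_distance_matrix(collapsed)
cat(sprintf("cophenetic correlation of the UPGMA tree: %.3f\n",
            cophenetic_correlation(bs$tree, d)))
cat(sprintf("clade support: %d clades, median BP %.2f, median AU %.2f\n",
            nrow(bs$support), stats::median(bs$support$bp),
            stats::median(bs$support$au)))
cat("dendrogram:\n", bs$newick, "\n")
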