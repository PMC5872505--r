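#!/usr/bin/env Rscript
# Stage 6: cross-species transferability and the UPGMA dendrogram.
#
# (a) Desk-scale: regenerate the published percent columns from the
#     bundled amplified-marker counts.
# (b) Synthetic: summarize the simulated species screen, cluster the
#     co-amplified binary profiles with UPGMA, write the Newick tree.

library(cilmark)

tt_ref <- reference_table("transferability")
cat("published transferability (percent of 164-marker panel):\n")
ok <- pct(tt_ref$amplified_total, 164) == tt_ref$pct_of_panel
cat(sprintf("  percent-of-panel identities hold for %d/%d species rows\n",
            sum(ok), nrow(tt_ref)))

species <- read_pcr_scores("results/panel/species_scores.tsv",
                           panel_manifest("wheat_sp", "recipient"))
tt <- summarize_transferability(species$matrix, species$meta,
                                wheat_id = "wheat_sp")
print(tt[, c("species", "amplified_total", "pct_of_panel",
             "pct_polymorphic_vs_wheat")])

co <- coamplified_marker_set(species$matrix)
cat(sprintf("co-amplified markers: %d of %d\n", length(co),
            nrow(species$matrix)))
d <- binary_distance_matrix(species$matrix[co, , drop = FALSE],
                            metric = "simple_matching")
tree <- upgma(d)
write.table(tt, "results/transferability.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(d, "results/species_distances.tsv", sep = "\t", quote = FALSE,
            col.names = NA)
write_newick(tree, "results/species_upgma.nwk")
cat("wrote results/transferability.tsv, results/species_distances.tsv,",
    "results/species_upgma.nwk\n")
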