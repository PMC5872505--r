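#!/usr/bin/env Rscript
# Stage 1: generate the synthetic wheat x wild-rye marker panel.
#
# No raw marker matrix is distributed for the study design this workflow
# follows, so the analyses run on a generative twin: 14 donor chromosomes,
# nine addition lines, six arm-translocation lines, seven N-recombination
# lines, ~30% monomorphic markers, a codominant class, CIL-based
# interaction SNPs, and call-rate missingness. Everything downstream reads
# the files written here.

library(cilmark)

seed <- as.integer(Sys.getenv("CILMARK_SEED", "20260926"))
dir.create("results/panel", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed, markers_per_chromosome = 800)
sim <- simulate_panel(cfg)
sp <- simulate_species_matrix(cfg, n_markers = 164)

write_dart_onerow(sim$dart$matrix, sim$dart$meta, "results/panel/dart_onerow.csv")
write_pcr_scores(sim$pcr$matrix, sim$pcr$meta, "results/panel/pcr_scores.tsv")
write_panel_manifest(sim$manifest, "results/panel/manifest.yml")
write_pcr_scores(sp$matrix, sp$meta, "results/panel/species_scores.tsv")
write_newick(sp$tree, "results/panel/species_truth.nwk")
# ground truth is not serialized: it is re-derivable by rerunning with the
# same seed

cat(sprintf("panel: %d DArT markers, %d PCR markers, %d genotypes (seed %d)\n",
            nrow(sim$dart$matrix), nrow(sim$pcr$matrix),
            nrow(sim$manifest), seed))
cat(sprintf("species screen: %d markers x %d species\n",
            nrow(sp$matrix), ncol(sp$matrix)))
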