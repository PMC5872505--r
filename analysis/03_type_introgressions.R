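#!/usr/bin/env Rscript
# Stage 3: the core set logic — locate alien chromosomes, derive
# chromosome-specific, arm-specific and CIL-based marker sets, and write
# the full per-marker classification report plus per-chromosome Venn
# tables. run_pipeline() chains the stages so the counts funnel is logged.

library(cilmark)

manifest <- read_panel_manifest("results/panel/manifest.yml")
dart <- read_dart_onerow("results/panel/dart_onerow.csv", manifest)
pcr <- read_pcr_scores("results/panel/pcr_scores.tsv", manifest)

res <- run_pipeline(dart = dart, pcr = pcr, manifest = manifest,
                    out_dir = "results/typing")

cat("marker funnel:\n")
print(res$funnel)
spec <- table(res$classification$specific_chromosome)
cat("chromosome-specific markers per alien chromosome:\n")
print(spec)
cat(sprintf("CIL-based SNPs: %d (%d line-specific, %d common)\n",
            nrow(res$cil),
            res$cil_summary$totals$line_specific,
            res$cil_summary$totals$common_dedup))
cat("reports under results/typing/\n")
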