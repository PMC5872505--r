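#!/usr/bin/env Rscript
# Stage 2: quality-filter the DArT SNPs (call rate >= 85%, reproducibility
# >= 95%) and classify every marker's polymorphism between the recipient
# and donor parents.

library(cilmark)

manifest <- read_panel_manifest("results/panel/manifest.yml")
dart <- read_dart_onerow("results/panel/dart_onerow.csv", manifest)
pcr <- read_pcr_scores("results/panel/pcr_scores.tsv", manifest)

flt <- filter_quality(dart$matrix, dart$meta,
                      min_call_rate = 0.85, min_reproducibility = 0.95)
cat(sprintf("DArT quality filter: %d of %d markers retained\n",
            nrow(flt$matrix), nrow(dart$matrix)))

calls <- rbind(
  classify_polymorphism(flt$matrix, flt$meta, manifest = manifest),
  classify_polymorphism(pcr$matrix, pcr$meta, manifest = manifest))
summary <- summarize_polymorphism(calls)
print(summary)

dir.create("results", showWarnings = FALSE)
write.table(summary, "results/polymorphism_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote results/polymorphism_summary.tsv\n")
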