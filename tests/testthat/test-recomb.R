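test_that("arm calls need one silent arm and enough positives", {
  expect_equal(arm_call_counts(0, 2, min_arm_evidence = 3)$call, "uncertain")
  expect_equal(arm_call_counts(0, 48, pcr_long = 1)$call, "long")
  expect_equal(arm_call_counts(160, 0, pcr_short = 2)$call, "short")
  expect_equal(arm_call_counts(0, 0)$call, "uncertain")
  expect_equal(arm_call_counts(5, 4)$call, "uncertain")   # both arms positive
  expect_equal(arm_call_counts(3, 0)$call, "short")       # threshold inclusive
  expect_equal(arm_call_counts(2, 0)$call, "uncertain")
})

test_that("fragment arms are called per line from arm-specific marker sets", {
  sim <- simulate_panel(quiet_config(seed = 51, markers_per_chromosome = 120))
  res <- run_pipeline(dart = sim$dart, pcr = sim$pcr, manifest = sim$manifest)
  ac <- res$arm_calls
  rec <- sim$manifest[sim$manifest$role == "recombination", ]
  true_arm <- rec$arm[match(ac$line, rec$sample_id)]
  callable <- pmax(ac$short_total, ac$long_total) >= 3
  expect_true(all(ac$call[callable] == true_arm[callable]))
  expect_true(all(ac$call[!callable] == "uncertain"))
  # the opposite arm never shows positives on a noise-free panel
  expect_true(all(ifelse(true_arm == "short", ac$long_total,
                         ac$short_total) == 0))
})

test_that("arm calls are stable under platform subsetting when one platform suffices", {
  sim <- simulate_panel(quiet_config(seed = 52, markers_per_chromosome = 120))
  res <- run_pipeline(dart = sim$dart, pcr = sim$pcr, manifest = sim$manifest)
  dart_only <- call_fragment_arm(list(DArT = sim$dart$matrix), sim$manifest,
                                 res$classification)
  both <- res$arm_calls
  ok <- pmax(dart_only$short_total, dart_only$long_total) >= 3
  expect_true(any(ok))
  expect_equal(dart_only$call[ok], both$call[ok])
})

test_that("graphical genotypes track alien, recipient and missing states in position order", {
  sim <- simulate_panel(quiet_config(seed = 53, markers_per_chromosome = 80))
  res <- run_pipeline(dart = sim$dart, manifest = sim$manifest)
  gg <- build_graphical_genotype(sim$dart$matrix, sim$dart$meta,
                                 res$classification, "N",
                                 manifest = sim$manifest)
  expect_true(all(tapply(gg$position_bp, gg$line,
                         function(p) all(diff(p) >= 0))))
  add_track <- gg[gg$line == "add_N", ]
  expect_true(all(add_track$state == "alien"))       # whole chromosome
  cs_track <- gg[gg$line == "recipient", ]
  expect_true(all(cs_track$state == "recipient"))    # no alien segment
  # every tracked marker appears exactly once per line
  expect_true(all(table(gg$line, gg$marker_id) == 1))
})

test_that("recombinant alien blocks coincide exactly with the simulated segment", {
  sim <- simulate_panel(quiet_config(seed = 54, markers_per_chromosome = 150))
  res <- run_pipeline(dart = sim$dart, manifest = sim$manifest)
  gg <- build_graphical_genotype(sim$dart$matrix, sim$dart$meta,
                                 res$classification, "N",
                                 manifest = sim$manifest)
  segs <- sim$truth$segments
  for (line in unique(sim$manifest$sample_id[
    sim$manifest$role == "recombination"])) {
    tr <- gg[gg$line == line, ]
    seg <- segs[segs$line == line, ]
    inside <- tr$position_bp >= seg$start_bp & tr$position_bp <= seg$end_bp
    expect_equal(tr$state == "alien", inside, info = line)
  }
})

test_that("bins are maximal alien runs whose marker counts add up", {
  gg <- data.frame(
    line = "L1",
    marker_id = paste0("m", 1:8),
    recipient_chromosome = "3B",
    position_bp = c(10, 20, 30, 40, 50, 60, 70, 80),
    state = c("recipient", "alien", "alien", "missing", "alien",
              "recipient", "alien", "alien"),
    stringsAsFactors = FALSE)
  b <- summarize_bins(gg)
  expect_equal(nrow(b), 3)                     # missing breaks a run
  expect_equal(b$start_bp, c(20, 50, 70))
  expect_equal(b$end_bp, c(30, 50, 80))
  expect_equal(sum(b$n_markers), sum(gg$state == "alien"))

  none <- summarize_bins(transform(gg, state = "recipient"))
  expect_equal(nrow(none), 0)
  whole <- summarize_bins(transform(gg, state = "alien"))
  expect_equal(nrow(whole), 1)
  expect_equal(whole$n_markers, 8)
})

test_that("BED export writes 0-based half-open state stretches", {
  gg <- data.frame(line = "L1", marker_id = paste0("m", 1:4),
                   recipient_chromosome = "3B",
                   position_bp = c(100, 200, 300, 400),
                   state = c("alien", "alien", "recipient", "recipient"),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_genotype_bed(gg, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, c(99, 299))
  expect_equal(bed$V3, c(200, 400))
  expect_equal(bed$V5, c("alien", "recipient"))
})

test_that("asking for an unpositioned chromosome fails informatively", {
  sim <- simulate_panel(quiet_config(seed = 55, markers_per_chromosome = 5))
  res <- run_pipeline(dart = sim$dart, manifest = sim$manifest)
  expect_error(build_graphical_genotype(sim$dart$matrix, sim$dart$meta,
                                        res$classification, "B",
                                        manifest = sim$manifest),
               "no positioned markers")
})
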