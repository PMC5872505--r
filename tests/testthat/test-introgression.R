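# Hand-built panel for the set logic. Columns follow tiny_manifest():
# CS LR add_A add_B add_C tr_AS tr_AL rec_A1 rec_A2
tiny_typing_matrix <- function() {
  tiny_matrix(list(
    donor_only = c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),  # chromosome not in panel
    spec_A     = c(0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L),  # A-specific, short arm
    spec_A_l   = c(0L, 1L, 1L, 0L, 0L, 0L, 1L, 0L, 1L),  # A-specific, long arm
    spec_A_b   = c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L),  # both translocations
    spec_A_u   = c(0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),  # untransmitted segment
    spec_B     = c(0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),  # B-specific
    co_AB      = c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),  # co-amplified
    all_nine   = c(0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),  # every addition line
    bg_short   = c(0L, 1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L),  # translocation only
    codom      = c(1L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L)   # codominant class
  ))
}

test_that("alien location keeps addition-line positives and matches a row scan", {
  mf <- tiny_manifest()
  m <- tiny_typing_matrix()
  got <- locate_alien_markers(m, mf)
  expect_false("donor_only" %in% got)     # positive only in the donor
  expect_true("all_nine" %in% got)        # positive in every addition line
  expect_true("codom" %in% got)           # score-2 counts as positive

  # random panels against an explicit per-marker loop
  sim <- simulate_panel(quiet_config(seed = 31, markers_per_chromosome = 10,
                                     call_rate_mean = 0.9,
                                     call_rate_sd = 0.05))
  sm <- sim$dart$matrix
  adds <- sim$manifest$sample_id[sim$manifest$role == "addition"]
  want <- rownames(sm)[vapply(seq_len(nrow(sm)), function(i)
    any(!is.na(sm[i, adds]) & sm[i, adds] >= 1), TRUE)]
  expect_identical(locate_alien_markers(sm, sim$manifest), want)
})

test_that("chromosome-specific assignment separates single-line from co-amplified", {
  mf <- tiny_manifest()
  m <- tiny_typing_matrix()
  spec <- assign_chromosome_specific(m, mf)
  get <- function(id, col) spec[spec$marker_id == id, col][[1]]
  expect_equal(get("spec_A", "specific_chromosome"), "A")
  expect_equal(get("spec_B", "specific_chromosome"), "B")
  expect_true(is.na(get("co_AB", "specific_chromosome")))
  expect_setequal(get("co_AB", "co_amplified_chromosomes"), c("A", "B"))
  expect_true(is.na(get("all_nine", "specific_chromosome")))

  # specific sets are pairwise disjoint by construction: one label each
  lab <- spec$specific_chromosome[!is.na(spec$specific_chromosome)]
  expect_true(all(table(spec$marker_id[!is.na(spec$specific_chromosome)]) == 1))
  expect_true(all(lab %in% c("A", "B", "C")))
})

test_that("arm assignment and Venn regions follow the three-way overlap", {
  mf <- tiny_manifest()
  m <- tiny_typing_matrix()
  spec <- assign_chromosome_specific(m, mf)
  arms <- assign_arm_specific(m, mf, spec)
  a <- arms$assignments
  get <- function(id, col) a[a$marker_id == id, col]
  expect_equal(get("spec_A", "arm"), "short")
  expect_equal(get("spec_A_l", "arm"), "long")
  expect_equal(get("spec_A_b", "arm"), "both")
  expect_equal(get("spec_A_u", "segment_flag"), "untransmitted_segment")
  expect_equal(get("bg_short", "segment_flag"), "background_interaction")
  expect_equal(get("bg_short", "arm"), "none")

  v <- arms$venn[arms$venn$chromosome == "A", ]
  # direct set enumeration over the ten hand-scored markers
  expect_equal(v$addition_short_only, 1)  # spec_A
  expect_equal(v$addition_long_only, 1)   # spec_A_l
  expect_equal(v$addition_both, 1)        # spec_A_b
  expect_equal(v$addition_only, 1)        # spec_A_u
  expect_equal(v$short_only, 1)           # bg_short
  expect_equal(v$long_only, 0)
  expect_equal(v$short_long_only, 0)
  # region counts partition the universe of involved markers
  expect_equal(sum(unlist(v[-1])), nrow(a[a$chromosome == "A", ]))
})

test_that("arm and Venn sets agree with set algebra on synthetic translocations", {
  sim <- simulate_panel(quiet_config(seed = 32, markers_per_chromosome = 40))
  res <- run_pipeline(dart = sim$dart, pcr = sim$pcr, manifest = sim$manifest)
  tm <- sim$truth$markers
  pm <- sim$truth$pcr_markers
  arm_of <- function(ids) ifelse(grepl("^pcr", ids),
                                 pm$arm[match(ids, pm$marker_id)],
                                 tm$arm[match(ids, tm$marker_id)])
  cls <- res$classification
  for (ch in c("I", "J", "N")) {
    spec_ids <- cls$marker_id[!is.na(cls$specific_chromosome) &
                                cls$specific_chromosome == ch]
    truth_arm <- arm_of(spec_ids)
    got_arm <- cls$arm[match(spec_ids, cls$marker_id)]
    expect_equal(got_arm, truth_arm, info = ch)
    v <- res$venn[res$venn$chromosome == ch, ]
    expect_equal(v$addition_short_only, sum(truth_arm == "short"))
    expect_equal(v$addition_long_only, sum(truth_arm == "long"))
  }
})

test_that("CIL-based SNPs require parents at zero and split by line count", {
  mf <- tiny_manifest()
  m <- tiny_matrix(list(
    cil_one   = c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
    cil_three = c(0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
    in_donor  = c(0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
    in_recip  = c(1L, 0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),
    na_recip  = c(NA, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
    na_donor  = c(0L, NA, 1L, 0L, 0L, 0L, 0L, 0L, 0L)
  ))
  cil <- find_cil_based_snps(m, mf)
  expect_setequal(cil$marker_id, c("cil_one", "cil_three", "na_donor"))
  expect_equal(cil$cil_category[cil$marker_id == "cil_one"], "line_specific")
  expect_equal(cil$line_specific_to[cil$marker_id == "cil_one"], "A")
  expect_equal(cil$cil_category[cil$marker_id == "cil_three"], "common")
  # missing recipient can never qualify; missing donor can
  expect_false("na_recip" %in% cil$marker_id)

  s <- summarize_cil_snps(cil, mf)
  expect_equal(s$totals$common_dedup + s$totals$line_specific,
               s$totals$total)
  # per-line common counts multi-count shared SNPs
  expect_equal(sum(s$per_line$common), 3)
  expect_equal(s$totals$common_dedup, 1)
})

test_that("injected interaction SNPs are recovered exactly on noise-free panels", {
  sim <- simulate_panel(quiet_config(seed = 33, markers_per_chromosome = 30))
  cil <- find_cil_based_snps(sim$dart$matrix, sim$manifest)
  tm <- sim$truth$markers
  adds <- sim$manifest$sample_id[sim$manifest$role == "addition"]
  injected <- tm$marker_id[tm$type == "interaction" &
                             vapply(tm$carriers, function(cs)
                               any(adds %in% cs), TRUE)]
  expect_setequal(cil$marker_id, injected)
})

test_that("typing assignments are invariant under marker-row permutation", {
  sim <- simulate_panel(quiet_config(seed = 34, markers_per_chromosome = 10))
  m <- sim$dart$matrix
  mf <- sim$manifest
  spec <- assign_chromosome_specific(m, mf)
  set.seed(1)
  pr <- sample(nrow(m))
  spec_p <- assign_chromosome_specific(m[pr, ], mf)
  i <- match(spec$marker_id, spec_p$marker_id)
  expect_equal(spec_p$specific_chromosome[i], spec$specific_chromosome)
})
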