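species_fixture <- function() {
  # markers x species; d1/d2 DNA-origin, r1/r2/r3 RNA-origin
  m <- rbind(
    d1 = c(donor = 1L, spA = 1L, spB = 0L, wheat = 0L),
    d2 = c(donor = 1L, spA = 0L, spB = 0L, wheat = 1L),
    r1 = c(donor = 1L, spA = 1L, spB = 1L, wheat = 1L),
    r2 = c(donor = 1L, spA = 2L, spB = 0L, wheat = 1L),
    r3 = c(donor = 1L, spA = 0L, spB = 0L, wheat = 0L))
  list(matrix = score_matrix(m, allow_missing = FALSE),
       meta = marker_meta(rownames(m), platform = "PCR",
                          source = c("DNA", "DNA", "RNA", "RNA", "RNA")))
}

test_that("transferability rows count amplification and wheat polymorphism", {
  fx <- species_fixture()
  tt <- summarize_transferability(fx$matrix, fx$meta, wheat_id = "wheat")
  donor <- tt[tt$species == "donor", ]
  expect_equal(donor$amplified_total, 5)
  expect_equal(donor$pct_of_panel, 100L)      # positive control
  expect_equal(donor$amplified_dna, 2)
  expect_equal(donor$amplified_rna, 3)

  spA <- tt[tt$species == "spA", ]
  expect_equal(spA$amplified_total, 3)
  expect_equal(spA$pct_of_panel, pct(3, 5))
  # polymorphic vs wheat: d1 (absent in wheat) and r2 (size difference) of 3
  expect_equal(spA$pct_polymorphic_vs_wheat, pct(2, 3))
  expect_equal(spA$pct_polymorphic_dna, pct(1, 1))
  expect_equal(spA$pct_polymorphic_rna, pct(1, 2))

  wheat <- tt[tt$species == "wheat", ]
  expect_true(is.na(wheat$pct_polymorphic_vs_wheat))

  # a species amplifying nothing reports zero with a flag
  m0 <- fx$matrix
  m0[, "spB"] <- 0L
  t0 <- summarize_transferability(m0, fx$meta, wheat_id = "wheat")
  expect_equal(t0$pct_of_panel[t0$species == "spB"], 0L)
  expect_true(t0$no_amplification[t0$species == "spB"])
})

test_that("transferability equals direct counting on random matrices", {
  set.seed(61)
  for (i in 1:10) {
    m <- matrix(sample(0:2, 40 * 6, replace = TRUE, prob = c(.4, .5, .1)),
                40, 6, dimnames = list(paste0("m", 1:40), paste0("s", 1:6)))
    meta <- marker_meta(rownames(m), platform = "PCR",
                        source = sample(c("DNA", "RNA"), 40, replace = TRUE))
    tt <- summarize_transferability(score_matrix(m, allow_missing = FALSE),
                                    meta, wheat_id = "s1")
    for (sp in paste0("s", 2:6)) {
      amp <- m[, sp] >= 1
      expect_equal(tt$amplified_total[tt$species == sp], sum(amp))
      poly <- amp & (m[, "s1"] == 0 |
                       (m[, sp] != m[, "s1"] &
                          (m[, sp] == 2 | m[, "s1"] == 2)))
      expect_equal(tt$pct_polymorphic_vs_wheat[tt$species == sp],
                   pct(sum(poly), sum(amp)))
    }
  }
})

test_that("co-amplified set keeps markers seen in two or more species", {
  fx <- species_fixture()
  co <- coamplified_marker_set(fx$matrix)
  expect_setequal(co, c("d1", "d2", "r1", "r2"))   # r3 is donor-only
  set.seed(62)
  m <- matrix(rbinom(200, 1, 0.4), 40, 5,
              dimnames = list(paste0("m", 1:40), paste0("s", 1:5)))
  got <- coamplified_marker_set(score_matrix(m, allow_missing = FALSE))
  expect_identical(got, rownames(m)[rowSums(m >= 1) >= 2])
})

test_that("binary distances follow the metric formulas", {
  m <- score_matrix(rbind(m1 = c(a = 1L, b = 1L, c = 0L),
                          m2 = c(a = 0L, b = 0L, c = 1L),
                          m3 = c(a = 1L, b = 1L, c = 0L),
                          m4 = c(a = 0L, b = 0L, c = 1L)),
                    allow_missing = FALSE)
  d_sm <- binary_distance_matrix(m, "simple_matching")
  expect_equal(d_sm["a", "b"], 0)          # identical profiles
  expect_equal(d_sm["a", "c"], 1)          # complementary profiles
  expect_equal(diag(d_sm), c(a = 0, b = 0, c = 0))
  expect_equal(d_sm, t(d_sm))

  set.seed(63)
  r <- matrix(rbinom(60, 1, 0.5), 20, 3,
              dimnames = list(paste0("m", 1:20), c("x", "y", "z")))
  rm <- score_matrix(r, allow_missing = FALSE)
  d1 <- binary_distance_matrix(rm, "simple_matching")
  d2 <- binary_distance_matrix(rm, "jaccard")
  for (p in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    a <- r[, p[1]] >= 1
    b <- r[, p[2]] >= 1
    expect_equal(d1[p[1], p[2]], 1 - mean(a == b))
    expect_equal(d2[p[1], p[2]], 1 - sum(a & b) / sum(a | b))
  }
})

test_that("UPGMA matches closed forms on two and three taxa", {
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(d2)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(unname(tr$edge.length), c(0.2, 0.2))

  labs <- c("A", "B", "C")
  d3 <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
               dimnames = list(labs, labs))
  tr3 <- upgma(d3)
  cp <- ape::cophenetic.phylo(tr3)
  expect_equal(cp["A", "B"], 0.2)          # cherry at height 0.1
  expect_equal(cp["A", "C"], 0.6)          # root at height 0.3
  expect_equal(cp["B", "C"], 0.6)
  depths <- leaf_depths(tr3)
  expect_equal(unname(depths), rep(0.3, 3))
})

test_that("UPGMA equals average-linkage agglomeration and is ultrametric", {
  set.seed(64)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    x <- matrix(rnorm(n * 4), n)
    rownames(x) <- paste0("t", seq_len(n))
    d <- as.matrix(dist(x))
    tr <- upgma(d)
    # independent oracle: stats::hclust average linkage, compared through
    # cophenetic distances (checks topology and heights together)
    hc <- hclust(as.dist(d), method = "average")
    want <- as.matrix(cophenetic(hc))
    got <- ape::cophenetic.phylo(tr)[rownames(want), colnames(want)]
    expect_equal(got, want, tolerance = 1e-9)
    depths <- leaf_depths(tr)
    expect_lt(max(depths) - min(depths), 1e-9 * max(depths))
  }
})

test_that("UPGMA is invariant to taxon input order", {
  set.seed(65)
  x <- matrix(rnorm(24), 6)
  rownames(x) <- paste0("t", 1:6)
  d <- as.matrix(dist(x))
  tr <- upgma(d)
  perm <- sample(6)
  tr_p <- upgma(d[perm, perm])
  labs <- rownames(d)
  expect_equal(ape::cophenetic.phylo(tr_p)[labs, labs],
               ape::cophenetic.phylo(tr)[labs, labs], tolerance = 1e-12)
})

test_that("degenerate distance input is rejected", {
  bad <- matrix(c(0, NA, NA, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(upgma(bad), "finite")
  neg <- matrix(c(0, -.1, -.1, 0), 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(upgma(neg), "non-negative")
  asym <- matrix(c(0, .1, .3, 0), 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(upgma(asym), "symmetric")
})

test_that("species matrices honour the generating hierarchy", {
  # a clock-like loss hierarchy: every leaf is the same total loss from the
  # root, so expected profile distances are ultrametric and UPGMA should
  # recover the generating topology from enough markers
  clock <- paste0("(((donor_sp:0.03,close_sp1:0.03):0.05,",
                  "(close_sp2:0.04,close_sp3:0.04):0.04):0.07,",
                  "((out_sp1:0.05,out_sp2:0.05):0.05,",
                  "(out_sp3:0.06,out_sp4:0.06):0.04):0.05);")
  cfg <- quiet_config(seed = 66, species_tree = clock)
  sp <- simulate_species_matrix(cfg, n_markers = 1500)
  expect_equal(unname(sp$matrix[, sp$donor]),
               rep(1L, nrow(sp$matrix)))          # donor pre-screened panel
  co <- coamplified_marker_set(sp$matrix)
  d <- binary_distance_matrix(sp$matrix[co, , drop = FALSE])
  tr <- upgma(d)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                         ape::unroot(sp$tree))), 0)
})

test_that("degenerate loss probabilities give full or empty profiles", {
  zero <- quiet_config(seed = 67, species_tree = paste0(
    "((donor_sp:0,close_sp1:0):0,(out_sp1:0,out_sp2:0):0);"))
  sp <- simulate_species_matrix(zero, n_markers = 50)
  expect_true(all(sp$matrix == 1L))               # loss probability zero
  one <- quiet_config(seed = 68, species_tree = paste0(
    "((donor_sp:0,close_sp1:1):0,(out_sp1:1,out_sp2:1):0);"))
  sp1 <- simulate_species_matrix(one, n_markers = 50)
  expect_true(all(sp1$matrix[, c("out_sp1", "out_sp2", "close_sp1")] == 0L))
})
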