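# Seeded synthetic marker panels with full ground truth.
#
# The generator emulates the structure of a wheat x wild-relative
# introgression study: a tetraploid donor with 14 chromosomes (labelled
# A..N), nine of which are carried by disomic addition lines; three
# chromosomes with short/long arm-translocation lines; seven recombination
# lines carrying terminal fragments of one chromosome; ~30% of markers
# monomorphic between the two genomes; a small codominant class; CIL-based
# interaction SNPs absent from both parents; call-rate-driven missingness
# and optional genotyping error.

DONOR_CHROMOSOMES <- LETTERS[1:14]
DEFAULT_ADDITIONS <- c("A", "E", "F", "H", "I", "J", "K", "L", "N")

#' Simulation configuration
#'
#' Defaults mirror the study design the generator emulates: 14 donor
#' chromosomes of which 9 appear as addition lines, translocations for three
#' chromosomes, seven recombination lines on chromosome N, 30% monomorphic
#' markers, a ~1% codominant class, and interaction SNPs at 13% of the base
#' marker count.
#'
#' @param seed integer seed; every draw is reproducible given it.
#' @param n_donor_chromosomes donor chromosome count (labels `A`, `B`, ...).
#' @param additions chromosome labels carried by disomic addition lines.
#' @param markers_per_chromosome DArT markers simulated per donor
#'   chromosome; 800 gives a panel on the scale of a filtered DArT-seq SNP
#'   set (~11,000 markers).
#' @param frac_monomorphic fraction of markers monomorphic between donor and
#'   recipient genomes.
#' @param frac_codominant fraction of polymorphic markers of the codominant
#'   class (recipient shows the SNP allele, donor both alleles).
#' @param call_rate_mean,call_rate_sd per-marker call-rate distribution
#'   (normal, truncated to `[0.5, 1]`); cells go missing at `1 - call_rate`.
#' @param reproducibility_mean,reproducibility_sd per-marker reported
#'   reproducibility distribution (same truncated-normal form).
#' @param interaction_snp_rate interaction (CIL-based) SNPs as a fraction of
#'   the base marker count.
#' @param interaction_single_line_prob probability an interaction SNP is
#'   carried by a single line rather than shared.
#' @param translocations chromosomes with short+long arm-translocation lines.
#' @param recombinations data.frame `chromosome`, `arm`, `breakpoint`
#'   (fraction of the arm, measured from the telomere) — one row per
#'   recombination line. The default seven N-lines span a near-empty
#'   fragment up to nearly whole arms.
#' @param genotyping_error_rate per-cell score-flip probability.
#' @param hg_fidelity probability a marker's wheat-chromosome correspondence
#'   points into its chromosome's true homoeologous group.
#' @param n_pcr_per_chromosome PCR markers per donor chromosome.
#' @param pcr_frac_size_poly fraction of polymorphic PCR markers that are
#'   size-polymorphic (scored 2 in carriers) rather than presence/absence.
#' @param chrom_length_bp,centromere_frac wheat-scale coordinate substrate:
#'   positions are uniform on `[1, chrom_length_bp]`, the short arm lies
#'   below `centromere_frac * chrom_length_bp`.
#' @param n_species,species_tree transferability screen: leaf count is taken
#'   from the Newick `species_tree` whose edge lengths are per-edge marker
#'   loss probabilities away from the donor.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_donor_chromosomes = 14,
                       additions = DEFAULT_ADDITIONS,
                       markers_per_chromosome = 800,
                       frac_monomorphic = 0.30,
                       frac_codominant = 0.011,
                       call_rate_mean = 0.95,
                       call_rate_sd = 0.04,
                       reproducibility_mean = 0.99,
                       reproducibility_sd = 0.015,
                       interaction_snp_rate = 0.13,
                       interaction_single_line_prob = 0.85,
                       translocations = c("I", "J", "N"),
                       recombinations = default_recombinations(),
                       genotyping_error_rate = 0,
                       hg_fidelity = 0.9,
                       n_pcr_per_chromosome = 5,
                       pcr_frac_size_poly = 0.06,
                       chrom_length_bp = 8e8,
                       centromere_frac = 0.45,
                       species_tree = default_species_tree()) {
  cfg <- list(seed = as.integer(seed),
              n_donor_chromosomes = n_donor_chromosomes,
              additions = additions,
              markers_per_chromosome = markers_per_chromosome,
              frac_monomorphic = frac_monomorphic,
              frac_codominant = frac_codominant,
              call_rate_mean = call_rate_mean,
              call_rate_sd = call_rate_sd,
              reproducibility_mean = reproducibility_mean,
              reproducibility_sd = reproducibility_sd,
              interaction_snp_rate = interaction_snp_rate,
              interaction_single_line_prob = interaction_single_line_prob,
              translocations = translocations,
              recombinations = recombinations,
              genotyping_error_rate = genotyping_error_rate,
              hg_fidelity = hg_fidelity,
              n_pcr_per_chromosome = n_pcr_per_chromosome,
              pcr_frac_size_poly = pcr_frac_size_poly,
              chrom_length_bp = chrom_length_bp,
              centromere_frac = centromere_frac,
              species_tree = species_tree)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fracs <- c("frac_monomorphic", "frac_codominant", "interaction_snp_rate",
             "interaction_single_line_prob", "genotyping_error_rate",
             "hg_fidelity", "pcr_frac_size_poly", "call_rate_mean",
             "reproducibility_mean", "centromere_frac")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("config field ", f, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_donor_chromosomes < 1 ||
      cfg$n_donor_chromosomes > length(LETTERS)) {
    stop("n_donor_chromosomes out of range", call. = FALSE)
  }
  chroms <- DONOR_CHROMOSOMES[seq_len(cfg$n_donor_chromosomes)]
  if (!all(cfg$additions %in% chroms)) {
    stop("addition chromosomes must be among the donor chromosomes",
         call. = FALSE)
  }
  if (!all(cfg$translocations %in% cfg$additions)) {
    stop("translocation chromosomes must have addition lines", call. = FALSE)
  }
  rec <- cfg$recombinations
  if (nrow(rec)) {
    stopifnot(all(rec$arm %in% c("short", "long")))
    if (any(rec$breakpoint <= 0 | rec$breakpoint >= 1)) {
      stop("recombination breakpoints must lie in (0, 1)", call. = FALSE)
    }
    if (!all(rec$chromosome %in% cfg$additions)) {
      stop("recombination chromosomes must have addition lines", call. = FALSE)
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

default_recombinations <- function() {
  data.frame(chromosome = "N",
             arm = c("long", "short", "short", "long", "short", "short",
                     "long"),
             breakpoint = c(0.012, 0.55, 0.25, 0.35, 0.5, 0.98, 0.96),
             stringsAsFactors = FALSE)
}

# Per-edge lengths are marker-loss probabilities away from the donor; the
# 12-leaf grouping mirrors a Triticeae-like panel: the donor's close
# perennials retain most markers, annual outgroups far fewer.
default_species_tree <- function() {
  paste0("(((donor_sp:0.005,close_sp1:0.28):0.12,close_sp2:0.33):0.1,",
         "(close_sp3:0.42,((out_sp1:0.2,out_sp2:0.2):0.35,",
         "((out_sp3:0.15,out_sp4:0.15):0.3,((out_sp5:0.2,out_sp6:0.25):0.05,",
         "(out_sp7:0.18,wheat_sp:0.2):0.08):0.3):0.2):0.2):0.08);")
}

true_homoeologous_group <- function(chrom) {
  (match(chrom, DONOR_CHROMOSOMES) - 1) %% 7 + 1
}

#' Simulate a marker x genotype panel
#'
#' Generates a DArT SNP matrix, a PCR band matrix, the matching panel
#' manifest and a full ground-truth record. Deterministic given
#' `config$seed`. Addition lines carry every marker of their chromosome;
#' translocation lines one arm; recombination lines only markers inside the
#' simulated terminal donor segment; monomorphic markers score positive in
#' the recipient too; interaction SNPs are positive in their carrier lines
#' and absent from both parents.
#'
#' @param config [sim_config()].
#' @return list: `dart` (matrix + meta), `pcr` (matrix + meta), `manifest`,
#'   `truth` (per-marker and per-line ground truth).
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- DONOR_CHROMOSOMES[seq_len(config$n_donor_chromosomes)]
  manifest <- build_sim_manifest(config)
  L <- config$chrom_length_bp
  centromere <- config$centromere_frac * L

  n_base <- config$markers_per_chromosome * length(chroms)
  base <- data.frame(
    marker_id = sprintf("snp_%05d", seq_len(n_base)),
    chromosome = rep(chroms, each = config$markers_per_chromosome),
    position = sample.int(L, n_base, replace = TRUE),
    stringsAsFactors = FALSE)
  base$arm <- ifelse(base$position <= centromere, "short", "long")
  type_draw <- stats::runif(n_base)
  base$type <- ifelse(type_draw < config$frac_monomorphic, "monomorphic",
                      ifelse(type_draw < config$frac_monomorphic +
                               (1 - config$frac_monomorphic) *
                               config$frac_codominant,
                             "codominant", "polymorphic"))

  n_int <- round(config$interaction_snp_rate * n_base)
  intr <- if (n_int > 0) {
    carriers <- interaction_carriers(n_int, manifest, config)
    data.frame(marker_id = sprintf("cil_%05d", seq_len(n_int)),
               chromosome = NA_character_,
               position = sample.int(L, n_int, replace = TRUE),
               arm = NA_character_, type = "interaction",
               stringsAsFactors = FALSE) -> d
    d$carriers <- I(carriers)
    d
  } else {
    NULL
  }

  truth_markers <- base
  truth_markers$carriers <- I(rep(list(NULL), nrow(base)))
  if (!is.null(intr)) truth_markers <- rbind(truth_markers, intr)

  segments <- line_segments(manifest, config)
  call_rate <- pmin(1, pmax(0.5, stats::rnorm(nrow(truth_markers),
                                              config$call_rate_mean,
                                              config$call_rate_sd)))
  dart <- score_panel(truth_markers, manifest, segments, config,
                      platform = "DArT", call_rate = call_rate)
  meta <- dart_meta(truth_markers, config, call_rate)

  pcr_truth <- simulate_pcr_markers(config, chroms)
  pcr <- score_panel(pcr_truth, manifest, segments, config, platform = "PCR")
  pcr_meta <- marker_meta(marker_id = pcr_truth$marker_id, platform = "PCR",
                          source = pcr_truth$source)

  truth_markers$expected_specific <- truth_markers$type == "polymorphic" &
    truth_markers$chromosome %in% config$additions
  truth_markers$true_hg <- ifelse(is.na(truth_markers$chromosome), NA,
                                  true_homoeologous_group(truth_markers$chromosome))
  list(dart = list(matrix = dart, meta = meta),
       pcr = list(matrix = pcr, meta = pcr_meta),
       manifest = manifest,
       truth = list(markers = truth_markers, pcr_markers = pcr_truth,
                    segments = segments,
                    true_hg = stats::setNames(true_homoeologous_group(chroms),
                                              chroms)))
}

build_sim_manifest <- function(config) {
  rec <- config$recombinations
  panel_manifest(
    sample_id = c("recipient", "donor",
                  paste0("add_", config$additions),
                  paste0("tr_", rep(config$translocations, each = 2),
                         c("S", "L")),
                  if (nrow(rec)) paste0("rec_", rec$chromosome,
                                        seq_len(nrow(rec)))),
    role = c("recipient", "donor",
             rep("addition", length(config$additions)),
             rep("translocation", 2 * length(config$translocations)),
             rep("recombination", nrow(rec))),
    chromosome = c(NA, NA, config$additions,
                   rep(config$translocations, each = 2),
                   rec$chromosome),
    arm = c(NA, NA, rep(NA, length(config$additions)),
            rep(c("short", "long"), length(config$translocations)),
            rec$arm),
    index = c(rep(NA, 2 + length(config$additions) +
                    2 * length(config$translocations)),
              if (nrow(rec)) seq_len(nrow(rec))))
}

# Carried alien intervals per introgression line, in donor-chromosome
# coordinates. Terminal recombinant segments start at the telomere of their
# arm and extend a breakpoint fraction toward the centromere.
line_segments <- function(manifest, config) {
  L <- config$chrom_length_bp
  centromere <- config$centromere_frac * L
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    role <- manifest$role[i]
    if (!role %in% c("addition", "translocation", "recombination")) next
    ch <- manifest$chromosome[i]
    if (role == "addition") {
      iv <- c(1, L)
    } else if (role == "translocation") {
      iv <- if (manifest$arm[i] == "short") c(1, centromere)
            else c(centromere + 1, L)
    } else {
      b <- config$recombinations$breakpoint[manifest$index[i]]
      iv <- if (manifest$arm[i] == "short") c(1, b * centromere)
            else c(L - b * (L - centromere) + 1, L)
    }
    rows[[length(rows) + 1]] <- data.frame(
      line = manifest$sample_id[i], chromosome = ch,
      arm = if (is.na(manifest$arm[i])) "both" else manifest$arm[i],
      start_bp = iv[1], end_bp = iv[2], stringsAsFactors = FALSE)
  }
  rbind_rows(rows)
}

interaction_carriers <- function(n_int, manifest, config) {
  lines <- manifest$sample_id[manifest$role %in% c("addition",
                                                   "translocation")]
  lapply(seq_len(n_int), function(i) {
    k <- if (stats::runif(1) < config$interaction_single_line_prob) 1
         else sample(2:min(5, length(lines)), 1)
    sample(lines, k)
  })
}

# Score one platform's marker set across the panel.
score_panel <- function(markers, manifest, segments, config, platform,
                        call_rate = NULL) {
  n <- nrow(markers)
  samples <- manifest$sample_id
  m <- base::matrix(0L, n, length(samples),
                    dimnames = list(markers$marker_id, samples))
  recipient_state <- ifelse(markers$type == "monomorphic", 1L,
                            ifelse(markers$type == "codominant", 1L, 0L))
  donor_state <- ifelse(markers$type == "monomorphic", 1L,
                        ifelse(markers$type == "codominant", 2L,
                               ifelse(markers$type == "interaction", 0L,
                                      ifelse(markers$type == "size_polymorphic",
                                             2L, 1L))))
  carrier_state <- ifelse(markers$type %in% c("codominant",
                                              "size_polymorphic"), 2L,
                          ifelse(markers$type == "monomorphic", 1L, 1L))
  for (s in samples) {
    role <- manifest$role[manifest$sample_id == s]
    if (role == "recipient") {
      m[, s] <- recipient_state
    } else if (role == "donor") {
      m[, s] <- donor_state
    } else {
      m[, s] <- recipient_state
      seg <- segments[segments$line == s, , drop = FALSE]
      carried <- !is.na(markers$chromosome) &
        markers$chromosome == seg$chromosome &
        markers$position >= seg$start_bp & markers$position <= seg$end_bp
      m[carried, s] <- carrier_state[carried]
      if (!is.null(markers$carriers)) {
        hit <- vapply(markers$carriers, function(cs) s %in% cs, TRUE)
        m[hit, s] <- 1L
      }
    }
  }
  if (config$genotyping_error_rate > 0) {
    flip <- base::matrix(stats::runif(length(m)) <
                           config$genotyping_error_rate, nrow(m))
    m[flip] <- ifelse(m[flip] == 0L, 1L, ifelse(m[flip] == 1L, 0L, 1L))
  }
  if (platform == "DArT" && !is.null(call_rate) && any(call_rate < 1)) {
    drop <- base::matrix(stats::runif(length(m)) >
                           rep(call_rate, ncol(m)), nrow(m))
    m[drop] <- NA_integer_
  }
  m
}

dart_meta <- function(markers, config, call_rate) {
  n <- nrow(markers)
  hg <- true_homoeologous_group(markers$chromosome)
  faithful <- stats::runif(n) < config$hg_fidelity
  group <- integer(n)
  for (i in seq_len(n)) {
    group[i] <- if (is.na(hg[i])) {
      sample(1:7, 1)
    } else if (faithful[i]) {
      hg[i]
    } else {
      sample(setdiff(1:7, hg[i]), 1)
    }
  }
  subgenome <- sample(c("A", "B", "D"), n, replace = TRUE)
  repro <- pmin(1, pmax(0.5, stats::rnorm(n, config$reproducibility_mean,
                                          config$reproducibility_sd)))
  marker_meta(marker_id = markers$marker_id, platform = "DArT",
              source = sample(c("DNA", "RNA"), n, replace = TRUE),
              call_rate = call_rate, reproducibility = repro,
              wheat_chromosome = paste0(group, subgenome),
              position_bp = markers$position)
}

simulate_pcr_markers <- function(config, chroms) {
  n <- config$n_pcr_per_chromosome * length(chroms)
  if (n == 0) {
    return(data.frame(marker_id = character(0), chromosome = character(0),
                      position = numeric(0), arm = character(0),
                      type = character(0), source = character(0),
                      stringsAsFactors = FALSE))
  }
  pos <- sample.int(config$chrom_length_bp, n, replace = TRUE)
  type_draw <- stats::runif(n)
  type <- ifelse(type_draw < config$frac_monomorphic, "monomorphic",
                 ifelse(type_draw < config$frac_monomorphic +
                          (1 - config$frac_monomorphic) *
                          config$pcr_frac_size_poly,
                        "size_polymorphic", "polymorphic"))
  data.frame(marker_id = sprintf("pcr_%03d", seq_len(n)),
             chromosome = rep(chroms, each = config$n_pcr_per_chromosome),
             position = pos,
             arm = ifelse(pos <= config$centromere_frac *
                            config$chrom_length_bp, "short", "long"),
             type = type,
             source = sample(c("DNA", "RNA"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate a cross-species amplification matrix
#'
#' Markers start amplified in the donor and are lost along the edges of a
#' species hierarchy (edge length = loss probability), so closer species
#' share more positive markers. Only markers amplified in the donor are
#' kept, mimicking a donor-pre-screened panel; the donor column is
#' all-positive.
#'
#' @param config [sim_config()]; `species_tree` supplies the hierarchy and
#'   its leaf labels.
#' @param n_markers panel size.
#' @param seed optional override of `config$seed`.
#' @return list with `matrix` (markers x species scores, 0/1), `meta`
#'   (marker source DNA/RNA), `tree` (the generating `phylo`), and
#'   `donor` (the donor leaf label).
#' @export
simulate_species_matrix <- function(config = sim_config(), n_markers = 164,
                                    seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  tree <- ape::read.tree(text = config$species_tree)
  donor <- tree$tip.label[1]
  profiles <- NULL
  # rejection-sample until n_markers survive in the donor
  while (is.null(profiles) || nrow(profiles) < n_markers) {
    block <- evolve_loss(tree, donor, n = max(n_markers, 64))
    block <- block[block[, donor] == 1L, , drop = FALSE]
    profiles <- rbind(profiles, block)
  }
  profiles <- profiles[seq_len(n_markers), , drop = FALSE]
  rownames(profiles) <- sprintf("pcr_%03d", seq_len(n_markers))
  meta <- marker_meta(marker_id = rownames(profiles), platform = "PCR",
                      source = sample(c("DNA", "RNA"), n_markers,
                                      replace = TRUE))
  list(matrix = score_matrix(profiles, allow_missing = FALSE), meta = meta,
       tree = tree, donor = donor)
}

# Presence/absence evolution: start present at the node nearest the donor
# and lose along every edge, traversing the tree as an undirected graph
# rooted at the donor tip so the donor's own path sees (almost) no loss.
evolve_loss <- function(tree, donor, n) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  adj <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]
    b <- tree$edge[e, 2]
    w <- min(1, max(0, tree$edge.length[e]))
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  start <- match(donor, tree$tip.label)
  state <- base::matrix(0L, n, n_node)
  state[, start] <- 1L
  visited <- rep(FALSE, n_node)
  visited[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      u <- nb[k, 1]
      if (visited[u]) next
      visited[u] <- TRUE
      keep <- stats::runif(n) >= nb[k, 2]
      state[, u] <- state[, v] * as.integer(keep)
      queue <- c(queue, u)
    }
  }
  out <- state[, seq_len(n_tip), drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}
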