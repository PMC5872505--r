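# Set logic over the genotype panel: locating alien chromosomes, deriving
# chromosome-specific, arm-specific and CIL-based marker sets.
#
# "Positive" throughout means score 1 or 2 (the genotype shows the alien/SNP
# allele or band); a codominant 2 counts because an introgression line
# carries both the wheat and the alien complement. Missing calls are never
# evidence of presence or of absence.

#' Locate markers on alien chromosomes
#'
#' A polymorphic marker locates an alien chromosome when at least one
#' disomic addition line scores positive for it. Markers positive only in
#' the donor belong to donor chromosomes not represented in the panel.
#'
#' @param matrix score matrix restricted to polymorphic markers.
#' @param manifest [panel_manifest()].
#' @return character vector of alien-locating marker ids, matrix order.
#' @export
locate_alien_markers <- function(matrix, manifest) {
  check_manifest_matrix(matrix, manifest)
  adds <- addition_lines(manifest)
  if (nrow(adds) == 0) return(character(0))
  pos <- is_positive(matrix[, adds$sample_id, drop = FALSE])
  rownames(matrix)[rowSums(pos) >= 1]
}

#' Assign chromosome-specific markers
#'
#' A marker positive in exactly one addition line is specific to that line's
#' alien chromosome; positives in two or more lines are recorded as
#' co-amplified with no specific label.
#'
#' @param matrix score matrix restricted to alien-locating markers.
#' @param manifest [panel_manifest()].
#' @return data.frame with `marker_id`, `specific_chromosome` (`NA` when
#'   co-amplified) and `co_amplified_chromosomes` (list column).
#' @export
assign_chromosome_specific <- function(matrix, manifest) {
  check_manifest_matrix(matrix, manifest)
  adds <- addition_lines(manifest)
  pos <- is_positive(matrix[, adds$sample_id, drop = FALSE])
  n_pos <- rowSums(pos)
  chrom_hits <- apply(pos, 1, function(p) adds$chromosome[p], simplify = FALSE)
  spec <- rep(NA_character_, nrow(matrix))
  spec[n_pos == 1] <- vapply(chrom_hits[n_pos == 1], `[`, "", 1)
  co <- rep(list(character(0)), nrow(matrix))
  co[n_pos >= 2] <- chrom_hits[n_pos >= 2]
  data.frame(marker_id = rownames(matrix),
             specific_chromosome = spec,
             co_amplified_chromosomes = I(co),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign arm-specific markers and tabulate the three-way overlap
#'
#' For each alien chromosome that has arm-translocation lines, every
#' chromosome-specific marker is placed on an arm: positive in the short-arm
#' line only gives `short`, long only gives `long`, both gives `both`
#' (flagged — seen when one translocation is in fact a segment of the
#' other), and positive in the addition line but in neither translocation
#' flags a chromosome segment not transmitted to the translocation lines.
#' Markers positive in a translocation line but not in any addition line are
#' flagged as background-interaction polymorphisms and get no arm.
#'
#' @param matrix full polymorphic score matrix (needed to find
#'   translocation-only markers).
#' @param manifest [panel_manifest()].
#' @param specific result of [assign_chromosome_specific()].
#' @return list with `assignments` (marker_id, chromosome, arm,
#'   segment_flag) and `venn` (one row per chromosome: the seven regions of
#'   the addition/short/long overlap).
#' @export
assign_arm_specific <- function(matrix, manifest, specific) {
  check_manifest_matrix(matrix, manifest)
  chroms <- unique(manifest$chromosome[manifest$role == "translocation"])
  chroms <- chroms[!is.na(chroms)]
  assignments <- list()
  venn <- list()
  for (ch in sort(chroms)) {
    short_id <- manifest_samples(manifest, "translocation", ch, "short")
    long_id <- manifest_samples(manifest, "translocation", ch, "long")
    add_id <- manifest_samples(manifest, "addition", ch)
    if (length(short_id) == 0 && length(long_id) == 0) next
    spec_ids <- specific$marker_id[!is.na(specific$specific_chromosome) &
                                     specific$specific_chromosome == ch]
    in_short <- positive_in(matrix, short_id)
    in_long <- positive_in(matrix, long_id)
    in_add <- positive_in(matrix, add_id)
    # Universe: this chromosome's specific markers plus markers positive in a
    # translocation line but in no addition line (background-interaction
    # candidates). Markers co-amplified across addition lines stay out.
    any_add <- positive_in_any_addition(matrix, manifest)
    bg_ids <- rownames(matrix)[(in_short | in_long) & !any_add]
    ids <- union(spec_ids, bg_ids)
    s <- in_short[ids]
    l <- in_long[ids]
    a <- in_add[ids]
    is_spec <- ids %in% spec_ids
    arm <- rep("none", length(ids))
    arm[is_spec & s & !l] <- "short"
    arm[is_spec & !s & l] <- "long"
    arm[is_spec & s & l] <- "both"
    seg <- rep("none", length(ids))
    seg[is_spec & !s & !l] <- "untransmitted_segment"
    seg[!is_spec] <- "background_interaction"
    assignments[[ch]] <- data.frame(marker_id = ids, chromosome = ch,
                                    arm = arm, segment_flag = seg,
                                    stringsAsFactors = FALSE)
    venn[[ch]] <- data.frame(
      chromosome = ch,
      addition_only = sum(a & !s & !l),
      addition_short_only = sum(a & s & !l),
      addition_long_only = sum(a & !s & l),
      addition_both = sum(a & s & l),
      short_only = sum(!a & s & !l),
      long_only = sum(!a & !s & l),
      short_long_only = sum(!a & s & l),
      stringsAsFactors = FALSE)
  }
  list(assignments = rbind_rows(assignments), venn = rbind_rows(venn))
}

positive_in <- function(matrix, sample_id) {
  if (length(sample_id) == 0) {
    return(stats::setNames(rep(FALSE, nrow(matrix)), rownames(matrix)))
  }
  stats::setNames(is_positive(matrix[, sample_id[1]]), rownames(matrix))
}

positive_in_any_addition <- function(matrix, manifest) {
  adds <- addition_lines(manifest)
  if (nrow(adds) == 0) {
    return(stats::setNames(rep(FALSE, nrow(matrix)), rownames(matrix)))
  }
  stats::setNames(
    rowSums(is_positive(matrix[, adds$sample_id, drop = FALSE])) >= 1,
    rownames(matrix))
}

#' Find CIL-based SNPs
#'
#' CIL-based SNPs are polymorphisms created by the interaction between an
#' introgressed chromosome and the carrier genome: positive in at least one
#' addition line while both parents score 0 (a missing donor score also
#' qualifies; a missing recipient score never does). Markers positive in
#' exactly one addition line are line-specific, those shared by two or more
#' lines are common; the common total is de-duplicated across lines.
#'
#' @param matrix full (quality-filtered) score matrix.
#' @param manifest [panel_manifest()].
#' @return data.frame with `marker_id`, `cil_category` (`line_specific` or
#'   `common`), `line_specific_to`, `n_positive_lines`.
#' @export
find_cil_based_snps <- function(matrix, manifest) {
  check_manifest_matrix(matrix, manifest)
  adds <- addition_lines(manifest)
  rid <- recipient_id(manifest)
  did <- donor_id(manifest)
  r <- matrix[, rid]
  d <- if (is.na(did)) rep(NA_integer_, nrow(matrix)) else matrix[, did]
  pos <- is_positive(matrix[, adds$sample_id, drop = FALSE])
  n_pos <- rowSums(pos)
  cil <- !is.na(r) & r == 0L & (is.na(d) | d == 0L) & n_pos >= 1
  if (!any(cil)) {
    out <- data.frame(marker_id = character(0), cil_category = character(0),
                      line_specific_to = character(0),
                      n_positive_lines = integer(0), stringsAsFactors = FALSE)
    out$positive_lines <- I(list())
    return(out)
  }
  hits <- apply(pos[cil, , drop = FALSE], 1, function(p) adds$chromosome[p],
                simplify = FALSE)
  out <- data.frame(marker_id = rownames(matrix)[cil],
                    cil_category = ifelse(n_pos[cil] == 1, "line_specific",
                                          "common"),
                    line_specific_to = ifelse(n_pos[cil] == 1,
                                              vapply(hits, `[`, "", 1),
                                              NA_character_),
                    n_positive_lines = n_pos[cil],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$positive_lines <- I(hits)
  out
}

#' Summarize CIL-based SNPs per addition line
#'
#' Per-line counts multi-count common SNPs (a SNP shared by three lines
#' appears in three rows); the de-duplicated common total is reported once.
#'
#' @param cil result of [find_cil_based_snps()].
#' @param manifest [panel_manifest()].
#' @return list with `per_line` (chromosome, common, line_specific) and
#'   `totals` (deduplicated common, line_specific, total).
#' @export
summarize_cil_snps <- function(cil, manifest) {
  adds <- addition_lines(manifest)
  per_line <- do.call(rbind, lapply(adds$chromosome, function(ch) {
    common_here <- vapply(seq_len(nrow(cil)), function(i) {
      cil$cil_category[i] == "common" && ch %in% cil_lines(cil, i)
    }, TRUE)
    data.frame(chromosome = ch,
               common = sum(common_here),
               line_specific = sum(cil$cil_category == "line_specific" &
                                     cil$line_specific_to == ch, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(per_line = per_line,
       totals = data.frame(common_dedup = sum(cil$cil_category == "common"),
                           line_specific = sum(cil$cil_category == "line_specific"),
                           total = nrow(cil)))
}

# which addition chromosomes carry CIL snp i (stored via n_positive_lines
# only for line-specific; for common we re-derive from the attribute set in
# find_cil_based_snps when present, otherwise from line_specific_to)
cil_lines <- function(cil, i) {
  if (!is.null(cil$positive_lines)) return(cil$positive_lines[[i]])
  if (!is.na(cil$line_specific_to[i])) return(cil$line_specific_to[i])
  character(0)
}

#' Full marker classification table
#'
#' Convenience wrapper combining [locate_alien_markers()],
#' [assign_chromosome_specific()], [assign_arm_specific()] and
#' [find_cil_based_snps()] into the per-marker classification report.
#'
#' @param matrix quality-filtered score matrix.
#' @param meta marker metadata.
#' @param manifest [panel_manifest()].
#' @param calls optional precomputed [classify_polymorphism()] result.
#' @return list with `classification` (one row per marker), `venn`,
#'   `cil`, `calls`.
#' @export
classify_markers <- function(matrix, meta, manifest, calls = NULL) {
  if (is.null(calls)) {
    calls <- classify_polymorphism(matrix, meta, manifest = manifest)
  }
  poly_ids <- calls$marker_id[is_polymorphic(calls$status)]
  poly <- matrix[rownames(matrix) %in% poly_ids, , drop = FALSE]
  alien <- locate_alien_markers(poly, manifest)
  specific <- assign_chromosome_specific(
    poly[rownames(poly) %in% alien, , drop = FALSE], manifest)
  arms <- assign_arm_specific(poly, manifest, specific)
  cil <- find_cil_based_snps(matrix, manifest)

  cls <- data.frame(marker_id = rownames(matrix), stringsAsFactors = FALSE)
  cls$status <- calls$status[match(cls$marker_id, calls$marker_id)]
  cls$alien_locating <- cls$marker_id %in% alien
  cls$specific_chromosome <-
    specific$specific_chromosome[match(cls$marker_id, specific$marker_id)]
  co <- specific$co_amplified_chromosomes[match(cls$marker_id,
                                                specific$marker_id)]
  cls$co_amplified_chromosomes <- I(lapply(co, function(x)
    if (is.null(x)) character(0) else x))
  cls$arm <- "none"
  cls$segment_flag <- "none"
  if (!is.null(arms$assignments) && nrow(arms$assignments)) {
    i <- match(cls$marker_id, arms$assignments$marker_id)
    cls$arm <- ifelse(is.na(i), "none", arms$assignments$arm[i])
    cls$segment_flag <- ifelse(is.na(i), "none",
                               arms$assignments$segment_flag[i])
  }
  # chromosome-specific markers of chromosomes without translocation lines
  # cannot be arm-placed
  unplaced <- !is.na(cls$specific_chromosome) & cls$arm == "none" &
    cls$segment_flag == "none" &
    !cls$specific_chromosome %in% arms$assignments$chromosome
  cls$arm[unplaced] <- "unplaced"
  cls$cil_category <- "none"
  cls$line_specific_to <- NA_character_
  i <- match(cls$marker_id, cil$marker_id)
  cls$cil_category <- ifelse(is.na(i), "none", cil$cil_category[i])
  cls$line_specific_to <- ifelse(is.na(i), NA_character_,
                                 cil$line_specific_to[i])
  list(classification = cls, venn = arms$venn, cil = cil, calls = calls)
}
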