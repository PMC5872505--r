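# Homoeologous-group assignment by marker correspondence counting.
#
# Bread wheat carries seven homoeologous groups, each with one chromosome
# per subgenome (A, B, D). An alien chromosome is assigned to the group
# whose three wheat chromosomes absorb the most of its chromosome-specific
# markers' positional correspondences.

HG_GROUPS <- 1:7

#' Assign a homoeologous group from per-chromosome correspondence counts
#'
#' Sums the 21 per-wheat-chromosome marker counts within each homoeologous
#' group and returns the argmax group. The call is `ND` (not determined)
#' when total evidence is below `min_evidence` or when the top two group
#' sums tie (a warning lists the tied groups; no tie-break is invented).
#'
#' @param counts named numeric vector of marker counts; names are wheat
#'   chromosome labels `1A..7D` (missing labels count 0).
#' @param min_evidence minimum number of corresponding markers required for
#'   a call; default 5 — comfortably above the single-marker case that stays
#'   undetermined while far below any determined case.
#' @return list with `counts` (all 21), `group_sums` (length 7),
#'   `evidence_n`, and `assigned_group` (integer or `"ND"`).
#' @export
hg_assign_counts <- function(counts, min_evidence = 5) {
  bad <- setdiff(names(counts), WHEAT_CHROMOSOMES)
  if (length(bad)) {
    stop("unknown wheat chromosome label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  full <- stats::setNames(rep(0, length(WHEAT_CHROMOSOMES)), WHEAT_CHROMOSOMES)
  full[names(counts)] <- counts
  sums <- vapply(HG_GROUPS, function(g)
    sum(full[paste0(g, c("A", "B", "D"))]), 0)
  names(sums) <- HG_GROUPS
  evidence <- sum(full)
  top <- which(sums == max(sums))
  assigned <- if (evidence < min_evidence) {
    "ND"
  } else if (length(top) > 1) {
    warning("tied homoeologous groups: ", paste(top, collapse = ", "),
            call. = FALSE)
    "ND"
  } else {
    as.integer(top)
  }
  list(counts = full, group_sums = sums, evidence_n = evidence,
       assigned_group = assigned)
}

#' Assign homoeologous groups to alien chromosomes
#'
#' Tallies, per alien chromosome, the wheat-chromosome correspondences of
#' its chromosome-specific DArT markers (markers lacking a correspondence
#' label are excluded) and applies [hg_assign_counts()].
#'
#' @param classification marker classification table from
#'   [classify_markers()] (needs `marker_id`, `specific_chromosome`).
#' @param meta marker metadata carrying `platform` and `wheat_chromosome`.
#' @param alien_chromosomes labels to assign; default every chromosome with
#'   specific markers.
#' @param min_evidence see [hg_assign_counts()].
#' @param platform platforms whose markers carry trusted positional
#'   correspondence; PCR markers lack it, so the default is DArT only.
#' @return data.frame, one row per alien chromosome: the 21 counts, the 7
#'   group sums, `evidence_n` and `assigned_group`.
#' @export
assign_homoeologous_group <- function(classification, meta,
                                      alien_chromosomes = NULL,
                                      min_evidence = 5, platform = "DArT") {
  spec <- classification[!is.na(classification$specific_chromosome), ]
  if (is.null(alien_chromosomes)) {
    alien_chromosomes <- sort(unique(spec$specific_chromosome))
  }
  meta <- meta[meta$platform %in% platform, ]
  rows <- lapply(alien_chromosomes, function(ch) {
    ids <- spec$marker_id[spec$specific_chromosome == ch]
    wc <- meta$wheat_chromosome[meta$marker_id %in% ids]
    wc <- wc[!is.na(wc)]
    counts <- table(factor(wc, levels = WHEAT_CHROMOSOMES))
    hg <- hg_assign_counts(stats::setNames(as.numeric(counts), names(counts)),
                           min_evidence = min_evidence)
    cbind(data.frame(alien_chromosome = ch, stringsAsFactors = FALSE),
          as.data.frame(as.list(hg$counts), check.names = FALSE),
          as.data.frame(as.list(stats::setNames(hg$group_sums,
                                                paste0("HG", HG_GROUPS)))),
          data.frame(evidence_n = hg$evidence_n,
                     assigned_group = as.character(hg$assigned_group),
                     stringsAsFactors = FALSE))
  })
  rbind_rows(rows)
}
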