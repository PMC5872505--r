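# Recombinant-fragment localization and graphical genotyping along
# recipient-chromosome coordinates.

#' Call the arm of a recombinant fragment
#'
#' Counts a line's positives over the short- and long-arm-specific marker
#' sets of its chromosome (per platform) and calls the arm only when one arm
#' has positives, the other has none, and the total meets
#' `min_arm_evidence`; anything else is `uncertain`. The default threshold
#' of 3 keeps a two-marker fragment uncertain while accepting every clearly
#' separated fragment.
#'
#' @param short_count,long_count positive-marker counts per arm (totals
#'   across platforms, or give platform splits via `pcr_short`/`pcr_long`
#'   in which case the `*_count` arguments are the DArT counts).
#' @param pcr_short,pcr_long optional PCR positives, added to the totals.
#' @param min_arm_evidence minimum total positives for a call.
#' @return list with the per-arm totals and `call` in
#'   `{"short", "long", "uncertain"}`.
#' @export
arm_call_counts <- function(short_count, long_count, pcr_short = 0,
                            pcr_long = 0, min_arm_evidence = 3) {
  s <- short_count + pcr_short
  l <- long_count + pcr_long
  call <- if (s > 0 && l == 0 && s >= min_arm_evidence) {
    "short"
  } else if (l > 0 && s == 0 && l >= min_arm_evidence) {
    "long"
  } else {
    "uncertain"
  }
  list(short_total = s, long_total = l, call = call)
}

#' Call recombinant-fragment arms for every recombination line
#'
#' @param matrices named list of score matrices by platform (e.g.
#'   `list(DArT = ..., PCR = ...)`); any subset of platforms works.
#' @param manifest [panel_manifest()].
#' @param classification classification table with `marker_id`,
#'   `specific_chromosome`, `arm` (from [classify_markers()]); markers with
#'   arm `short`/`long` form the arm-specific sets.
#' @param min_arm_evidence see [arm_call_counts()].
#' @return data.frame: one row per recombination line with per-platform
#'   per-arm positive counts and the fragment arm call.
#' @export
call_fragment_arm <- function(matrices, manifest, classification,
                              min_arm_evidence = 3) {
  rec <- manifest[manifest$role == "recombination", , drop = FALSE]
  if (nrow(rec) == 0) return(NULL)
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    ch <- rec$chromosome[i]
    line <- rec$sample_id[i]
    counts <- list(short = 0, long = 0, pcr_short = 0, pcr_long = 0)
    for (platform in names(matrices)) {
      m <- matrices[[platform]]
      if (is.null(m) || !line %in% colnames(m)) next
      for (arm in c("short", "long")) {
        ids <- classification$marker_id[
          !is.na(classification$specific_chromosome) &
            classification$specific_chromosome == ch &
            classification$arm == arm]
        ids <- intersect(ids, rownames(m))
        n <- sum(is_positive(m[ids, line]))
        key <- if (toupper(platform) == "PCR") paste0("pcr_", arm) else arm
        counts[[key]] <- counts[[key]] + n
      }
    }
    ac <- arm_call_counts(counts$short, counts$long, counts$pcr_short,
                          counts$pcr_long, min_arm_evidence)
    data.frame(line = line, chromosome = ch, index = rec$index[i],
               pcr_short = counts$pcr_short, pcr_long = counts$pcr_long,
               dart_short = counts$short, dart_long = counts$long,
               short_total = ac$short_total, long_total = ac$long_total,
               call = ac$call, stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}

#' Graphical genotypes along a recipient chromosome
#'
#' Orders the chromosome-specific markers that correspond to one recipient
#' (wheat) chromosome by physical position and renders, per line, a track of
#' states: `alien` where the line scores 1 or 2, `recipient` where 0,
#' `missing` otherwise. Missing calls are shown as such, never interpolated.
#'
#' @param matrix score matrix.
#' @param meta marker metadata with `wheat_chromosome` and `position_bp`.
#' @param classification classification table; only markers specific to
#'   `alien_chromosome` are tracked.
#' @param alien_chromosome alien chromosome whose markers form the track.
#' @param recipient_chromosome wheat chromosome supplying the coordinates;
#'   default the modal correspondence among the specific markers.
#' @param lines sample ids to genotype; default every line of
#'   `alien_chromosome` in the manifest plus the parents.
#' @param manifest [panel_manifest()] (needed only for the `lines` default).
#' @return data.frame track: `line`, `marker_id`, `position_bp`, `state`,
#'   positions non-decreasing within each line.
#' @export
build_graphical_genotype <- function(matrix, meta, classification,
                                     alien_chromosome,
                                     recipient_chromosome = NULL,
                                     lines = NULL, manifest = NULL) {
  ids <- classification$marker_id[
    !is.na(classification$specific_chromosome) &
      classification$specific_chromosome == alien_chromosome]
  mm <- meta[meta$marker_id %in% ids & !is.na(meta$wheat_chromosome) &
               !is.na(meta$position_bp), , drop = FALSE]
  if (nrow(mm) == 0) {
    stop("no positioned markers specific to chromosome ", alien_chromosome,
         call. = FALSE)
  }
  if (is.null(recipient_chromosome)) {
    tab <- table(mm$wheat_chromosome)
    recipient_chromosome <- names(tab)[which.max(tab)]
  }
  mm <- mm[mm$wheat_chromosome == recipient_chromosome, , drop = FALSE]
  if (nrow(mm) == 0) {
    stop("no positioned markers for recipient chromosome ",
         recipient_chromosome, call. = FALSE)
  }
  mm <- mm[order(mm$position_bp, mm$marker_id), ]
  if (is.null(lines)) {
    if (is.null(manifest)) stop("give either lines or a manifest", call. = FALSE)
    keep <- (manifest$role %in% c("addition", "translocation", "recombination") &
               manifest$chromosome == alien_chromosome) |
      manifest$role %in% c("recipient", "donor")
    lines <- manifest$sample_id[keep]
  }
  tracks <- lapply(lines, function(line) {
    sc <- matrix[mm$marker_id, line]
    state <- ifelse(is.na(sc), "missing", ifelse(sc >= 1, "alien", "recipient"))
    data.frame(line = line, marker_id = mm$marker_id,
               recipient_chromosome = recipient_chromosome,
               position_bp = mm$position_bp, state = state,
               stringsAsFactors = FALSE)
  })
  rbind_rows(tracks)
}

#' Summarize alien bins of a graphical genotype
#'
#' A bin is a maximal run of consecutive alien-state markers along a line's
#' track (a missing call breaks a run). Bin boundaries are the outermost
#' marker positions — marker resolution is the only evidence, so no
#' midpoints are interpolated.
#'
#' @param genotypes track data.frame from [build_graphical_genotype()].
#' @return data.frame: `line`, `bin`, `start_bp`, `end_bp`, `n_markers`.
#' @export
summarize_bins <- function(genotypes) {
  rows <- lapply(split(genotypes, genotypes$line), function(tr) {
    tr <- tr[order(tr$position_bp, tr$marker_id), ]
    alien <- tr$state == "alien"
    if (!any(alien)) return(NULL)
    runs <- rle(alien)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- which(runs$values)
    data.frame(line = tr$line[1], bin = seq_along(keep),
               start_bp = tr$position_bp[starts[keep]],
               end_bp = tr$position_bp[ends[keep]],
               n_markers = runs$lengths[keep],
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  if (is.null(out)) {
    out <- data.frame(line = character(0), bin = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_markers = integer(0), stringsAsFactors = FALSE)
  }
  out
}

#' Export graphical genotypes as a BED-like track
#'
#' One 0-based half-open interval per marker state stretch, columns
#' `chrom, start, end, line, state`.
#'
#' @param genotypes track data.frame from [build_graphical_genotype()].
#' @param path output TSV path.
#' @export
write_genotype_bed <- function(genotypes, path) {
  rows <- lapply(split(genotypes, genotypes$line), function(tr) {
    tr <- tr[order(tr$position_bp, tr$marker_id), ]
    runs <- rle(tr$state)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    data.frame(chrom = tr$recipient_chromosome[1],
               start = tr$position_bp[starts] - 1,
               end = tr$position_bp[ends],
               line = tr$line[1], state = runs$values,
               stringsAsFactors = FALSE)
  })
  bed <- rbind_rows(rows)
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
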