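# Tabular IO: DArT one-row CSV, PCR score TSV, panel manifest YAML,
# classification report TSV, Newick trees.
#
# Parsing is strict by design: every cell must be a legal score or the reader
# raises, naming the offending row and column. Nothing is silently coerced.

DART_META_COLS <- c("marker_id", "clone_id", "wheat_chromosome", "position_bp",
                    "call_rate", "reproducibility")

#' Read a DArT-seq SNP one-row score file
#'
#' The one-row dialect carries one line per SNP with metadata columns
#' (`marker_id, clone_id, wheat_chromosome, position_bp, call_rate,
#' reproducibility`) followed by one score column per sample. Scores are
#' `0` (reference allele only), `1` (SNP allele only), `2` (both alleles);
#' `-` or an empty cell marks a missing call.
#'
#' @param path CSV file path.
#' @param manifest [panel_manifest()]; every manifest sample must match a
#'   score column exactly (case-sensitive).
#' @return list with `matrix` (score matrix, file order preserved) and
#'   `meta` (marker metadata with platform `"DArT"`).
#' @export
read_dart_onerow <- function(path, manifest) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = NULL)
  missing_meta <- setdiff(DART_META_COLS, names(raw))
  if (length(missing_meta)) {
    stop("DArT file lacks column(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  sample_cols <- setdiff(names(raw), DART_META_COLS)
  unmatched <- setdiff(manifest$sample_id, sample_cols)
  if (length(unmatched)) {
    stop("manifest samples without a matching score column: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  scores <- parse_scores(raw[sample_cols], raw$marker_id,
                         missing_tokens = c("-", ""))
  meta <- marker_meta(marker_id = raw$marker_id, platform = "DArT",
                      source = dart_source(raw),
                      call_rate = parse_num(raw$call_rate, "call_rate"),
                      reproducibility = parse_num(raw$reproducibility,
                                                  "reproducibility"),
                      wheat_chromosome = raw$wheat_chromosome,
                      position_bp = parse_num(raw$position_bp, "position_bp"))
  meta$clone_id <- raw$clone_id
  list(matrix = scores, meta = meta)
}

dart_source <- function(raw) {
  if ("source" %in% names(raw)) raw$source else "unknown"
}

#' Read a PCR band-score file
#'
#' Tab-separated with columns `marker_id`, `source` (`DNA`/`RNA`) and one
#' score column per genotype. Bands are scored `0` (absent) / `1` (present);
#' `2` flags the introgression-line band size of a size-polymorphic marker.
#' PCR scores carry no missing sentinel.
#'
#' @inheritParams read_dart_onerow
#' @return list with `matrix` and `meta` (platform `"PCR"`).
#' @export
read_pcr_scores <- function(path, manifest) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (!"marker_id" %in% names(raw)) {
    stop("PCR file lacks a marker_id column", call. = FALSE)
  }
  src <- if ("source" %in% names(raw)) raw$source else "unknown"
  sample_cols <- setdiff(names(raw), c("marker_id", "source"))
  unmatched <- setdiff(manifest$sample_id, sample_cols)
  if (length(unmatched)) {
    stop("manifest samples without a matching score column: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  scores <- parse_scores(raw[sample_cols], raw$marker_id,
                         missing_tokens = character(0))
  meta <- marker_meta(marker_id = raw$marker_id, platform = "PCR",
                      source = src)
  list(matrix = scores, meta = meta)
}

parse_scores <- function(cols, marker_ids, missing_tokens) {
  m <- matrix(NA_integer_, nrow = length(marker_ids), ncol = length(cols),
              dimnames = list(marker_ids, names(cols)))
  for (j in seq_along(cols)) {
    x <- trimws(cols[[j]])
    is_missing <- x %in% missing_tokens
    legal <- x %in% c("0", "1", "2")
    if (any(!legal & !is_missing)) {
      i <- which(!legal & !is_missing)[1]
      stop(sprintf("unknown score symbol '%s' at marker '%s', column '%s'",
                   x[i], marker_ids[i], names(cols)[j]), call. = FALSE)
    }
    m[legal, j] <- as.integer(x[legal])
  }
  score_matrix(m, allow_missing = length(missing_tokens) > 0)
}

parse_num <- function(x, what) {
  x <- trimws(x)
  x[x %in% c("", "-", "NA")] <- NA
  out <- suppressWarnings(as.numeric(x))
  if (any(is.na(out) & !is.na(x))) {
    stop("non-numeric ", what, " value: ", x[is.na(out) & !is.na(x)][1],
         call. = FALSE)
  }
  out
}

#' Write a DArT one-row score file
#'
#' Inverse of [read_dart_onerow()]; missing cells are written as `-`.
#'
#' @param matrix score matrix.
#' @param meta marker metadata aligned with the matrix rows.
#' @param path output CSV path.
#' @export
write_dart_onerow <- function(matrix, meta, path) {
  meta <- meta[match(rownames(matrix), meta$marker_id), ]
  scr <- matrix
  mode(scr) <- "character"
  scr[is.na(scr)] <- "-"
  out <- data.frame(marker_id = rownames(matrix),
                    clone_id = if ("clone_id" %in% names(meta)) meta$clone_id
                               else rownames(matrix),
                    wheat_chromosome = ifelse(is.na(meta$wheat_chromosome), "",
                                              meta$wheat_chromosome),
                    position_bp = ifelse(is.na(meta$position_bp), "",
                                         format(meta$position_bp, scientific = FALSE,
                                                trim = TRUE)),
                    call_rate = meta$call_rate,
                    reproducibility = meta$reproducibility,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(scr, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a PCR band-score file
#'
#' @inheritParams write_dart_onerow
#' @param path output TSV path.
#' @export
write_pcr_scores <- function(matrix, meta, path) {
  meta <- meta[match(rownames(matrix), meta$marker_id), ]
  out <- data.frame(marker_id = rownames(matrix), source = meta$source,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(matrix, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a panel manifest
#'
#' Manifests are YAML: a `samples` list with one key-value record per
#' genotype (`sample_id`, `role`, and where relevant `chromosome`, `arm`,
#' `index`, `display_name`).
#'
#' @param path YAML file path.
#' @return [panel_manifest()] data.frame.
#' @export
read_panel_manifest <- function(path) {
  doc <- yaml::read_yaml(path)
  recs <- doc$samples
  if (is.null(recs)) stop("manifest YAML lacks a 'samples' list", call. = FALSE)
  grab <- function(r, field, default) {
    v <- r[[field]]
    if (is.null(v)) default else v
  }
  panel_manifest(
    sample_id = vapply(recs, grab, "", field = "sample_id", default = NA_character_),
    role = vapply(recs, grab, "", field = "role", default = NA_character_),
    chromosome = vapply(recs, grab, "", field = "chromosome", default = NA_character_),
    arm = vapply(recs, grab, "", field = "arm", default = NA_character_),
    index = vapply(recs, function(r) as.integer(grab(r, "index", NA_integer_)), 1L),
    display_name = vapply(recs, function(r) as.character(grab(r, "display_name", NA_character_)), "")
  ) -> mf
  mf$display_name[is.na(mf$display_name)] <- mf$sample_id[is.na(mf$display_name)]
  mf
}

#' @rdname read_panel_manifest
#' @param manifest a [panel_manifest()].
#' @export
write_panel_manifest <- function(manifest, path) {
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- as.list(manifest[i, , drop = FALSE])
    r <- lapply(r, function(v) if (is.na(v)) NULL else v)
    Filter(Negate(is.null), r)
  })
  yaml::write_yaml(list(samples = recs), path)
  invisible(path)
}

#' Write / read the marker classification report
#'
#' One TSV row per marker carrying every classification field; the report
#' round-trips through [read_classification_report()].
#'
#' @param classification data.frame as returned by [classify_markers()].
#' @param path output TSV path.
#' @export
write_classification_report <- function(classification, path) {
  out <- classification
  out$co_amplified_chromosomes <-
    vapply(out$co_amplified_chromosomes, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_classification_report
#' @export
read_classification_report <- function(path) {
  out <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", na.strings = "")
  out$alien_locating <- out$alien_locating == "TRUE"
  out$co_amplified_chromosomes <- lapply(out$co_amplified_chromosomes,
                                         function(x) {
                                           if (is.na(x)) character(0)
                                           else strsplit(x, ",", fixed = TRUE)[[1]]
                                         })
  out
}

#' Write a tree in Newick format
#'
#' @param tree an `ape` \code{phylo} object (e.g. from [upgma()]).
#' @param path output file path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
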