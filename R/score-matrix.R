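# Core containers: score matrices, marker metadata, panel manifests.
#
# A score matrix is a plain integer matrix (markers in rows, genotypes in
# columns) with values in {0, 1, 2} and NA for missing DArT calls:
#   0 = reference allele only / band absent
#   1 = SNP allele only / band present
#   2 = both alleles / alternate band size (codominant)
# Marker metadata travels alongside as a data.frame keyed by marker_id.

SCORE_LEVELS <- c(0L, 1L, 2L)
WHEAT_CHROMOSOMES <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
MANIFEST_ROLES <- c("recipient", "donor", "addition", "translocation",
                    "recombination", "species")

#' Build a score matrix
#'
#' Validates and returns a markers x genotypes integer score matrix.
#'
#' @param scores matrix (or object coercible to one) of scores in
#'   `{0, 1, 2}`; `NA` marks a missing DArT call.
#' @param marker_ids,sample_ids optional dimnames; taken from `scores` when
#'   omitted. Marker ids must be unique.
#' @param allow_missing logical; PCR matrices must not contain missing cells.
#' @return integer matrix with marker ids as rownames and sample ids as
#'   colnames.
#' @export
score_matrix <- function(scores, marker_ids = rownames(scores),
                         sample_ids = colnames(scores),
                         allow_missing = TRUE) {
  m <- as.matrix(scores)
  storage.mode(m) <- "integer"
  if (is.null(marker_ids) || is.null(sample_ids)) {
    stop("score_matrix needs marker and sample identifiers", call. = FALSE)
  }
  if (anyDuplicated(marker_ids)) {
    stop("duplicated marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(m) <- as.character(marker_ids)
  colnames(m) <- as.character(sample_ids)
  bad <- !is.na(m) & !(m %in% SCORE_LEVELS)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("illegal score %s at marker '%s', sample '%s'",
                 m[bad][1], rownames(m)[idx[1]], colnames(m)[idx[2]]),
         call. = FALSE)
  }
  if (!allow_missing && anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing score at marker '%s', sample '%s' not allowed here",
                 rownames(m)[idx[1]], colnames(m)[idx[2]]), call. = FALSE)
  }
  m
}

#' Construct per-marker metadata
#'
#' @param marker_id character vector, unique.
#' @param platform `"PCR"` or `"DArT"` (recycled).
#' @param source marker origin, `"DNA"`, `"RNA"` or `"unknown"`.
#' @param call_rate,reproducibility fractions in `[0, 1]`; values given as
#'   percents (max > 1) are divided by 100.
#' @param wheat_chromosome corresponding recipient (wheat) chromosome label
#'   in `1A..7D`, or `NA`.
#' @param position_bp 1-based physical position on that chromosome, or `NA`.
#' @return data.frame with one row per marker.
#' @export
marker_meta <- function(marker_id, platform = "DArT", source = "unknown",
                        call_rate = 1, reproducibility = 1,
                        wheat_chromosome = NA_character_,
                        position_bp = NA_real_) {
  n <- length(marker_id)
  if (anyDuplicated(marker_id)) stop("duplicated marker ids in metadata", call. = FALSE)
  platform <- rep_len(as.character(platform), n)
  source <- rep_len(as.character(source), n)
  if (!all(platform %in% c("PCR", "DArT"))) stop("platform must be PCR or DArT", call. = FALSE)
  if (!all(source %in% c("DNA", "RNA", "unknown"))) {
    stop("source must be DNA, RNA or unknown", call. = FALSE)
  }
  call_rate <- normalize_rate(rep_len(call_rate, n), "call_rate")
  reproducibility <- normalize_rate(rep_len(reproducibility, n), "reproducibility")
  wheat_chromosome <- rep_len(as.character(wheat_chromosome), n)
  known <- is.na(wheat_chromosome) | wheat_chromosome == "" |
    wheat_chromosome %in% WHEAT_CHROMOSOMES
  if (!all(known)) {
    stop("unknown wheat chromosome label(s): ",
         paste(unique(wheat_chromosome[!known]), collapse = ", "), call. = FALSE)
  }
  wheat_chromosome[wheat_chromosome == ""] <- NA_character_
  position_bp <- as.numeric(rep_len(position_bp, n))
  if (any(!is.na(position_bp) & position_bp < 0)) {
    stop("position_bp must be non-negative", call. = FALSE)
  }
  data.frame(marker_id = as.character(marker_id), platform = platform,
             source = source, call_rate = call_rate,
             reproducibility = reproducibility,
             wheat_chromosome = wheat_chromosome, position_bp = position_bp,
             stringsAsFactors = FALSE)
}

# Rates may arrive as fractions (0-1) or percents (0-100); DArT exports use
# both dialects. Auto-detect on max > 1 and store fractions.
normalize_rate <- function(x, what) {
  x <- as.numeric(x)
  if (any(!is.na(x) & x > 1)) x <- x / 100
  if (any(!is.na(x) & (x < 0 | x > 1))) {
    stop(what, " must lie in [0, 1] (or [0, 100] as percent)", call. = FALSE)
  }
  x
}

#' Declare the genotype panel
#'
#' A panel manifest declares the role each sample column plays: the recipient
#' parent (wheat), the alien donor, disomic addition lines (one per alien
#' chromosome), arm-translocation lines, recombination lines, and unrelated
#' species used for transferability screens.
#'
#' @param sample_id character; must match score-matrix column names exactly
#'   (case-sensitive).
#' @param role one of `recipient`, `donor`, `addition`, `translocation`,
#'   `recombination`, `species`.
#' @param chromosome alien chromosome label; required for addition,
#'   translocation and recombination records.
#' @param arm `"short"` or `"long"`; required for translocation records.
#' @param index positive integer distinguishing recombination lines of the
#'   same chromosome.
#' @param display_name label used in reports and tree leaves; defaults to
#'   `sample_id`.
#' @return data.frame of class `panel_manifest`.
#' @export
panel_manifest <- function(sample_id, role, chromosome = NA_character_,
                           arm = NA_character_, index = NA_integer_,
                           display_name = sample_id) {
  n <- length(sample_id)
  mf <- data.frame(sample_id = as.character(sample_id),
                   role = rep_len(as.character(role), n),
                   chromosome = rep_len(as.character(chromosome), n),
                   arm = rep_len(as.character(arm), n),
                   index = rep_len(as.integer(index), n),
                   display_name = rep_len(as.character(display_name), n),
                   stringsAsFactors = FALSE)
  validate_manifest(mf)
}

validate_manifest <- function(mf) {
  if (anyDuplicated(mf$sample_id)) {
    stop("duplicated sample ids in manifest", call. = FALSE)
  }
  if (!all(mf$role %in% MANIFEST_ROLES)) {
    stop("unknown manifest role(s): ",
         paste(setdiff(mf$role, MANIFEST_ROLES), collapse = ", "), call. = FALSE)
  }
  if (sum(mf$role == "recipient") != 1) {
    stop("manifest must declare exactly one recipient", call. = FALSE)
  }
  if (sum(mf$role == "donor") > 1) {
    stop("manifest must declare at most one donor", call. = FALSE)
  }
  needs_chrom <- mf$role %in% c("addition", "translocation", "recombination")
  if (any(needs_chrom & (is.na(mf$chromosome) | mf$chromosome == ""))) {
    stop("addition/translocation/recombination records need a chromosome label",
         call. = FALSE)
  }
  tr <- mf$role == "translocation"
  if (any(tr & !(mf$arm %in% c("short", "long")))) {
    stop("translocation records need arm 'short' or 'long'", call. = FALSE)
  }
  if (anyDuplicated(paste(mf$chromosome[tr], mf$arm[tr]))) {
    stop("duplicate (chromosome, arm) translocation records", call. = FALSE)
  }
  if (any(mf$role == "recombination" & is.na(mf$index))) {
    stop("recombination records need an index", call. = FALSE)
  }
  # Lines pointing at a chromosome that has no addition record are legal but
  # flagged: downstream arm logic needs the whole-chromosome reference.
  added <- mf$chromosome[mf$role == "addition"]
  orphan <- unique(mf$chromosome[(tr | mf$role == "recombination") &
                                   !(mf$chromosome %in% added)])
  attr(mf, "orphan_chromosomes") <- orphan
  class(mf) <- c("panel_manifest", "data.frame")
  mf
}

manifest_samples <- function(manifest, role, chromosome = NULL, arm = NULL) {
  keep <- manifest$role == role
  if (!is.null(chromosome)) keep <- keep & manifest$chromosome %in% chromosome
  if (!is.null(arm)) keep <- keep & manifest$arm %in% arm
  manifest$sample_id[keep]
}

recipient_id <- function(manifest) manifest_samples(manifest, "recipient")
donor_id <- function(manifest) {
  id <- manifest_samples(manifest, "donor")
  if (length(id) == 0) NA_character_ else id
}
addition_lines <- function(manifest) {
  manifest[manifest$role == "addition", c("sample_id", "chromosome")]
}

check_manifest_matrix <- function(matrix, manifest) {
  missing <- setdiff(manifest$sample_id, colnames(matrix))
  if (length(missing)) {
    stop("manifest samples absent from score matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Positive = the genotype shows the marker's alien/SNP allele: score 1 or 2.
# A codominant 2 counts because the line carries both complements; NA never
# counts as evidence either way.
is_positive <- function(x) !is.na(x) & x >= 1L

#' Half-up integer percentage
#'
#' Percentages throughout the reports are rounded half-up to the nearest
#' integer (`floor(x + 0.5)`), the convention behind all printed summary
#' percentages. A zero denominator yields 0.
#'
#' @param num,den numerator and denominator counts.
#' @return integer percent(s).
#' @export
pct <- function(num, den) {
  out <- floor(100 * num / den + 0.5)
  out[rep_len(den == 0, length(out))] <- 0
  as.integer(out)
}

# rbind a list of data.frames that may contain NULLs; NULL when nothing left
rbind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
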