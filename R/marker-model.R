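# Marker quality filtering and polymorphism classification against the
# recipient (wheat) and donor (alien) parents.

POLYMORPHISM_STATUSES <- c("polymorphic_absent_in_recipient",
                           "polymorphic_codominant", "size_polymorphic",
                           "monomorphic", "non_amplified", "excluded")
POLYMORPHIC_STATUSES <- c("polymorphic_absent_in_recipient",
                          "polymorphic_codominant", "size_polymorphic")

#' Filter markers on call rate and reproducibility
#'
#' Retains exactly the markers whose call rate and reproducibility both meet
#' the thresholds (inclusive `>=`), preserving marker order. The default
#' call-rate threshold of 0.85 is the standard cut for reliable DArT-seq
#' SNPs; reproducibility defaults to 0.95.
#'
#' @param matrix score matrix.
#' @param meta marker metadata covering every matrix row.
#' @param min_call_rate,min_reproducibility fractions in `[0, 1]`.
#' @return list with the filtered `matrix` and `meta`.
#' @export
filter_quality <- function(matrix, meta, min_call_rate = 0.85,
                           min_reproducibility = 0.95) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_reproducibility >= 0, min_reproducibility <= 1)
  meta <- meta[match(rownames(matrix), meta$marker_id), ]
  if (anyNA(meta$marker_id)) {
    stop("metadata missing for some matrix markers", call. = FALSE)
  }
  keep <- meta$call_rate >= min_call_rate &
    meta$reproducibility >= min_reproducibility
  keep[is.na(keep)] <- FALSE
  list(matrix = matrix[keep, , drop = FALSE],
       meta = meta[keep, , drop = FALSE])
}

#' Classify marker polymorphism between the two parents
#'
#' Each marker's status is a pure function of its recipient score, donor
#' score and platform.
#'
#' DArT SNPs: donor 1 or 2 with recipient 0 is `polymorphic_absent_in_recipient`
#' (the SNP allele is absent from wheat); donor 2 with recipient 1 or 2 is
#' `polymorphic_codominant` (both alleles visible in the donor while wheat
#' already shows the SNP allele); a missing donor or recipient score is
#' `excluded` (polymorphism cannot be assessed); anything else is
#' `monomorphic`.
#'
#' PCR bands: donor 0 is `non_amplified`; donor 1 with recipient 0 is
#' `polymorphic_absent_in_recipient` (presence/absence); unequal scores
#' involving a 2 are `size_polymorphic`; equal positive scores are
#' `monomorphic`.
#'
#' @param matrix score matrix.
#' @param meta marker metadata (platform per marker).
#' @param recipient,donor sample ids of the two parents; default taken from
#'   `manifest` when given.
#' @param manifest optional [panel_manifest()] supplying the parent ids.
#' @return data.frame with `marker_id`, `platform`, `recipient_score`,
#'   `donor_score`, `status`.
#' @export
classify_polymorphism <- function(matrix, meta, recipient = NULL, donor = NULL,
                                  manifest = NULL) {
  if (!is.null(manifest)) {
    if (is.null(recipient)) recipient <- recipient_id(manifest)
    if (is.null(donor)) donor <- donor_id(manifest)
  }
  for (id in c(recipient, donor)) {
    if (is.na(id) || !id %in% colnames(matrix)) {
      stop("parent column '", id, "' absent from score matrix", call. = FALSE)
    }
  }
  meta <- meta[match(rownames(matrix), meta$marker_id), ]
  r <- matrix[, recipient]
  d <- matrix[, donor]
  status <- mapply(polymorphism_status, r, d, meta$platform, USE.NAMES = FALSE)
  data.frame(marker_id = rownames(matrix), platform = meta$platform,
             recipient_score = r, donor_score = d, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

polymorphism_status <- function(recipient, donor, platform) {
  if (platform == "DArT") {
    if (is.na(donor) || is.na(recipient)) return("excluded")
    if (donor %in% c(1L, 2L) && recipient == 0L) {
      return("polymorphic_absent_in_recipient")
    }
    if (donor == 2L && recipient %in% c(1L, 2L)) {
      return("polymorphic_codominant")
    }
    return("monomorphic")
  }
  # PCR: no missing sentinel exists in the format
  if (donor == 0L) return("non_amplified")
  if (donor == 1L && recipient == 0L) return("polymorphic_absent_in_recipient")
  if (donor != recipient && (donor == 2L || recipient == 2L)) {
    return("size_polymorphic")
  }
  if (donor == recipient) return("monomorphic")
  # donor 1, recipient 2 handled by the size rule above; donor 2 likewise.
  # Remaining pair is donor 1 / recipient 0 (handled) — defensive fallback:
  "monomorphic"
}

is_polymorphic <- function(status) status %in% POLYMORPHIC_STATUSES

#' Summarize polymorphism per platform
#'
#' Counts amplified, polymorphic and monomorphic markers per platform and
#' reports the polymorphic percentage of amplified markers, rounded half-up
#' (the convention of the printed summaries). "Amplified" means classifiable:
#' a positive donor band for PCR, a non-excluded call for DArT.
#'
#' @param calls result of [classify_polymorphism()].
#' @return data.frame with one row per platform.
#' @export
summarize_polymorphism <- function(calls) {
  do.call(rbind, lapply(split(calls, calls$platform), function(cc) {
    amplified <- sum(!cc$status %in% c("non_amplified", "excluded"))
    poly <- sum(is_polymorphic(cc$status))
    data.frame(platform = cc$platform[1], total = nrow(cc),
               amplified = amplified, polymorphic = poly,
               monomorphic = sum(cc$status == "monomorphic"),
               pct_polymorphic = pct(poly, amplified),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
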