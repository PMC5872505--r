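# Cross-species transferability summaries and UPGMA clustering of binary
# co-amplification profiles.

#' Summarize marker transferability across species
#'
#' Per species: amplified-marker counts split by marker source (DNA vs RNA
#' sequence origin), the percent of the screened panel amplified, and —
#' among the amplified markers — the percent polymorphic relative to wheat
#' (band absent in wheat, or a band-size difference flagged by a score 2).
#' Percentages are half-up integers; a species amplifying nothing reports 0
#' with `no_amplification = TRUE`. The wheat row's polymorphism columns are
#' `NA` (wheat is the comparator). A size-polymorphic 2 counts as amplified:
#' a band was produced.
#'
#' @param matrix score matrix, markers x species.
#' @param meta marker metadata with `source`.
#' @param wheat_id wheat (comparator) column name.
#' @param panel_size denominator for the percent-of-panel column; default
#'   the number of matrix rows.
#' @return data.frame, one row per species.
#' @export
summarize_transferability <- function(matrix, meta, wheat_id,
                                      panel_size = nrow(matrix)) {
  if (!wheat_id %in% colnames(matrix)) {
    stop("wheat column '", wheat_id, "' absent from species matrix",
         call. = FALSE)
  }
  meta <- meta[match(rownames(matrix), meta$marker_id), ]
  is_dna <- meta$source == "DNA"
  is_rna <- meta$source == "RNA"
  wheat <- matrix[, wheat_id]
  rows <- lapply(colnames(matrix), function(sp) {
    amp <- is_positive(matrix[, sp])
    poly <- amp & (wheat == 0L | (matrix[, sp] != wheat &
                                    (matrix[, sp] == 2L | wheat == 2L)))
    n_amp <- sum(amp)
    out <- data.frame(
      species = sp,
      amplified_dna = sum(amp & is_dna),
      amplified_rna = sum(amp & is_rna),
      amplified_total = n_amp,
      pct_of_panel = pct(n_amp, panel_size),
      pct_polymorphic_vs_wheat = pct(sum(poly), n_amp),
      pct_polymorphic_dna = pct(sum(poly & is_dna), sum(amp & is_dna)),
      pct_polymorphic_rna = pct(sum(poly & is_rna), sum(amp & is_rna)),
      no_amplification = n_amp == 0,
      stringsAsFactors = FALSE)
    if (sp == wheat_id) {
      out[c("pct_polymorphic_vs_wheat", "pct_polymorphic_dna",
            "pct_polymorphic_rna")] <- NA_integer_
    }
    out
  })
  rbind_rows(rows)
}

#' Markers co-amplified across species
#'
#' Markers amplified (score >= 1) in at least two species. Markers amplified
#' only in the donor are the donor-specific complement within the panel.
#'
#' @param matrix score matrix, markers x species.
#' @return character vector of co-amplified marker ids.
#' @export
coamplified_marker_set <- function(matrix) {
  rownames(matrix)[rowSums(is_positive(matrix)) >= 2]
}

#' Pairwise distances between binary amplification profiles
#'
#' Profiles are the presence/absence of amplification (score >= 1) over the
#' marker set. `simple_matching` uses both shared presences and shared
#' absences, matching how the scores were recorded:
#' `1 - matches / markers`. `jaccard` ignores shared absences:
#' `1 - |both positive| / |either positive|` (0 when both profiles are
#' empty).
#'
#' @param matrix score matrix, markers x species (typically restricted to
#'   [coamplified_marker_set()]).
#' @param metric `"simple_matching"` (default) or `"jaccard"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
binary_distance_matrix <- function(matrix, metric = c("simple_matching",
                                                      "jaccard")) {
  metric <- match.arg(metric)
  p <- is_positive(matrix)
  n_sp <- ncol(p)
  d <- base::matrix(0, n_sp, n_sp, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(n_sp)) {
    for (j in seq_len(n_sp)) {
      if (j <= i) next
      a <- p[, i]
      b <- p[, j]
      d[i, j] <- d[j, i] <- if (metric == "simple_matching") {
        1 - sum(a == b) / nrow(p)
      } else {
        either <- sum(a | b)
        if (either == 0) 0 else 1 - sum(a & b) / either
      }
    }
  }
  d
}

#' UPGMA clustering
#'
#' Unweighted pair-group method with arithmetic mean: iteratively merges the
#' closest pair of clusters, with inter-cluster distance the arithmetic mean
#' over all cross pairs and node height half the merge distance, producing a
#' rooted ultrametric tree. Ties are broken by the lexicographic order of
#' cluster labels (a cluster is labelled by its alphabetically first leaf),
#' making the result independent of input order.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   labelled dimnames, or a [stats::dist] object.
#' @return an `ape` \code{phylo} tree with branch lengths.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs labels", call. = FALSE)
  if (anyNA(d) || any(!is.finite(d))) {
    stop("distances must be finite and non-NA", call. = FALSE)
  }
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric",
                                       call. = FALSE)
  n <- nrow(d)
  if (n < 2) stop("need at least two taxa", call. = FALSE)
  labels <- rownames(d)
  if (anyDuplicated(labels)) stop("duplicated taxon labels", call. = FALSE)
  # active clusters: newick fragment, size, height, lexicographic label
  cl <- lapply(seq_len(n), function(i)
    list(newick = quote_label(labels[i]), size = 1, height = 0,
         label = labels[i]))
  D <- d
  dimnames(D) <- NULL
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]
        j <- active[jj]
        lab <- sort(c(cl[[i]]$label, cl[[j]]$label))
        cand <- list(i = i, j = j, d = D[i, j], lab = lab)
        if (is.null(best) || cand$d < best$d - 1e-15 ||
            (abs(cand$d - best$d) <= 1e-15 && lex_less(cand$lab, best$lab))) {
          best <- cand
        }
      }
    }
    i <- best$i
    j <- best$j
    h <- best$d / 2
    merged <- list(
      newick = sprintf("(%s:%.12g,%s:%.12g)", cl[[i]]$newick,
                       h - cl[[i]]$height, cl[[j]]$newick,
                       h - cl[[j]]$height),
      size = cl[[i]]$size + cl[[j]]$size, height = h,
      label = min(cl[[i]]$label, cl[[j]]$label))
    # arithmetic mean over all cross pairs = size-weighted update
    for (k in active) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        (cl[[i]]$size * D[i, k] + cl[[j]]$size * D[j, k]) / merged$size
    }
    cl[[i]] <- merged
    active <- setdiff(active, j)
  }
  tree <- ape::read.tree(text = paste0(cl[[active]]$newick, ";"))
  tree
}

quote_label <- function(x) {
  if (grepl("[^A-Za-z0-9_.-]", x)) paste0("'", gsub("'", "_", x), "'") else x
}

lex_less <- function(a, b) {
  if (a[1] != b[1]) return(a[1] < b[1])
  a[2] < b[2]
}

#' Root-to-leaf depths of an ultrametric tree
#'
#' Utility used to verify ultrametricity: returns each leaf's path length
#' from the root.
#'
#' @param tree a \code{phylo} object.
#' @return named numeric vector of leaf depths.
#' @export
leaf_depths <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  stats::setNames(depths[seq_along(tree$tip.label)], tree$tip.label)
}
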