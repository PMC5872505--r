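# End-to-end orchestration: read -> filter -> classify -> type ->
# homoeology -> recombinant mapping -> transferability/tree, with a marker
# count funnel logged at each stage.

#' Run the full introgression-typing pipeline
#'
#' Chains every analysis stage over a marker panel and writes all report
#' artifacts to `out_dir`: the per-marker classification TSV, polymorphism
#' and CIL summaries, homoeologous-group table, per-chromosome overlap
#' (Venn) tables, recombinant arm calls, graphical-genotype BED track, and —
#' when a species matrix is given — the transferability table, distance
#' matrix and UPGMA Newick tree. A `funnel.tsv` logs marker counts at each
#' stage.
#'
#' @param dart list with `matrix` and `meta` (e.g. from
#'   [read_dart_onerow()] or [simulate_panel()]), or `NULL`.
#' @param pcr list with `matrix` and `meta`, or `NULL`.
#' @param manifest [panel_manifest()].
#' @param species optional list with `matrix` and `meta` for the
#'   cross-species screen; its wheat column is `species_wheat_id`.
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @param min_call_rate,min_reproducibility quality thresholds
#'   ([filter_quality()]).
#' @param min_evidence homoeology evidence threshold ([hg_assign_counts()]).
#' @param min_arm_evidence arm-call threshold ([arm_call_counts()]).
#' @param metric distance metric for the species tree
#'   ([binary_distance_matrix()]).
#' @param species_wheat_id wheat column name in the species matrix.
#' @return (invisibly) a list with every intermediate result: `calls`,
#'   `classification`, `venn`, `cil`, `cil_summary`, `polymorphism_summary`,
#'   `hg`, `arm_calls`, `genotypes`, `bins`, `transferability`, `tree`,
#'   `funnel`.
#' @export
run_pipeline <- function(dart = NULL, pcr = NULL, manifest, species = NULL,
                         out_dir = NULL, min_call_rate = 0.85,
                         min_reproducibility = 0.95, min_evidence = 5,
                         min_arm_evidence = 3,
                         metric = "simple_matching",
                         species_wheat_id = NULL) {
  if (is.null(dart) && is.null(pcr)) {
    stop("need at least one of dart or pcr inputs", call. = FALSE)
  }
  funnel <- list()
  note <- function(stage, platform, n) {
    funnel[[length(funnel) + 1]] <<- data.frame(stage = stage,
                                                platform = platform, n = n,
                                                stringsAsFactors = FALSE)
  }

  if (!is.null(dart)) {
    note("input", "DArT", nrow(dart$matrix))
    flt <- filter_quality(dart$matrix, dart$meta, min_call_rate,
                          min_reproducibility)
    note("quality_filtered", "DArT", nrow(flt$matrix))
  } else {
    flt <- NULL
  }
  if (!is.null(pcr)) note("input", "PCR", nrow(pcr$matrix))

  # merge platforms into one matrix/meta for joint classification
  mats <- Filter(Negate(is.null), list(DArT = flt, PCR = pcr))
  all_samples <- manifest$sample_id
  joint <- do.call(rbind, lapply(mats, function(x)
    x$matrix[, all_samples, drop = FALSE]))
  rownames(joint) <- unlist(lapply(mats, function(x) rownames(x$matrix)),
                            use.names = FALSE)
  joint_meta <- do.call(rbind, lapply(mats, function(x)
    x$meta[match(rownames(x$matrix), x$meta$marker_id),
           c("marker_id", "platform", "source", "call_rate",
             "reproducibility", "wheat_chromosome", "position_bp")]))
  rownames(joint_meta) <- NULL

  typed <- classify_markers(joint, joint_meta, manifest)
  cls <- typed$classification
  poly_summary <- summarize_polymorphism(typed$calls)
  for (p in poly_summary$platform) {
    note("polymorphic", p,
         poly_summary$polymorphic[poly_summary$platform == p])
  }
  note("alien_locating", "all", sum(cls$alien_locating))
  note("chromosome_specific", "all", sum(!is.na(cls$specific_chromosome)))
  note("cil_based", "all", nrow(typed$cil))

  hg <- assign_homoeologous_group(cls, joint_meta,
                                  min_evidence = min_evidence)

  platform_mats <- lapply(mats, function(x) x$matrix)
  arm_calls <- call_fragment_arm(platform_mats, manifest, cls,
                                 min_arm_evidence = min_arm_evidence)

  genotypes <- NULL
  bins <- NULL
  rec_chroms <- unique(manifest$chromosome[manifest$role == "recombination"])
  rec_chroms <- intersect(rec_chroms, cls$specific_chromosome)
  for (ch in rec_chroms) {
    gg <- tryCatch(build_graphical_genotype(joint, joint_meta, cls, ch,
                                            manifest = manifest),
                   error = function(e) NULL)
    if (!is.null(gg)) {
      genotypes <- rbind(genotypes, gg)
      bins <- rbind(bins, summarize_bins(gg))
    }
  }

  transferability <- NULL
  dmat <- NULL
  tree <- NULL
  if (!is.null(species)) {
    if (is.null(species_wheat_id)) {
      stop("species matrix given without species_wheat_id", call. = FALSE)
    }
    transferability <- summarize_transferability(species$matrix,
                                                 species$meta,
                                                 species_wheat_id)
    co <- coamplified_marker_set(species$matrix)
    dmat <- binary_distance_matrix(
      species$matrix[co, , drop = FALSE], metric = metric)
    tree <- upgma(dmat)
  }

  funnel <- rbind_rows(funnel)
  cil_summary <- summarize_cil_snps(typed$cil, manifest)

  out <- list(calls = typed$calls, classification = cls, venn = typed$venn,
              cil = typed$cil, cil_summary = cil_summary,
              polymorphism_summary = poly_summary, hg = hg,
              arm_calls = arm_calls, genotypes = genotypes, bins = bins,
              transferability = transferability, distance_matrix = dmat,
              tree = tree, funnel = funnel)

  if (!is.null(out_dir)) write_pipeline_reports(out, out_dir)
  invisible(out)
}

write_pipeline_reports <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    if (is.null(x)) return()
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "")
  }
  write_classification_report(out$classification,
                              file.path(out_dir, "classification.tsv"))
  tsv(out$polymorphism_summary, "polymorphism_summary.tsv")
  tsv(out$venn, "arm_venn.tsv")
  tsv(out$cil_summary$per_line, "cil_per_line.tsv")
  tsv(out$hg, "homoeologous_groups.tsv")
  tsv(out$arm_calls, "arm_calls.tsv")
  tsv(out$bins, "recombinant_bins.tsv")
  tsv(out$funnel, "funnel.tsv")
  if (!is.null(out$genotypes)) {
    write_genotype_bed(out$genotypes,
                       file.path(out_dir, "graphical_genotypes.bed"))
  }
  tsv(out$transferability, "transferability.tsv")
  if (!is.null(out$distance_matrix)) {
    utils::write.table(out$distance_matrix,
                       file.path(out_dir, "species_distances.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(out$tree)) {
    write_newick(out$tree, file.path(out_dir, "species_tree.nwk"))
  }
  invisible(out_dir)
}

#' Bundled reference marker-count tables
#'
#' The package ships, as plain TSV under `inst/extdata/`, the published
#' summary counts of the wheat x *Leymus racemosus* introgression panel this
#' workflow was built around: the per-line marker funnel, the
#' homoeologous-group correspondence counts of the nine alien chromosomes,
#' the per-arm positives of the N-recombination lines, the per-line
#' CIL-based SNP counts, and the cross-species transferability table. These
#' drive the worked examples and the desk-scale reproduction checks.
#'
#' @param name one of `"marker_funnel"`, `"hg_counts"`, `"arm_counts"`,
#'   `"cil_counts"`, `"transferability"`.
#' @return data.frame.
#' @export
reference_table <- function(name = c("marker_funnel", "hg_counts",
                                     "arm_counts", "cil_counts",
                                     "transferability")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "cilmark",
                      mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
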