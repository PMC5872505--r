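# Tiny hand-built fixtures shared across the suite.

# A minimal panel: wheat recipient, alien donor, three addition lines
# (chromosomes A, B, C), short/long translocations of A, two recombination
# lines on A.
tiny_manifest <- function() {
  panel_manifest(
    sample_id = c("CS", "LR", "add_A", "add_B", "add_C", "tr_AS", "tr_AL",
                  "rec_A1", "rec_A2"),
    role = c("recipient", "donor", "addition", "addition", "addition",
             "translocation", "translocation", "recombination",
             "recombination"),
    chromosome = c(NA, NA, "A", "B", "C", "A", "A", "A", "A"),
    arm = c(NA, NA, NA, NA, NA, "short", "long", NA, NA),
    index = c(NA, NA, NA, NA, NA, NA, NA, 1L, 2L))
}

tiny_matrix <- function(rows, manifest = tiny_manifest()) {
  m <- do.call(rbind, rows)
  score_matrix(m, marker_ids = names(rows), sample_ids = manifest$sample_id)
}

# small noise-free simulation shared by several tests; `...` overrides any
# default, including the noise settings
quiet_config <- function(seed = 42, markers_per_chromosome = 60, ...) {
  defaults <- list(seed = seed,
                   markers_per_chromosome = markers_per_chromosome,
                   call_rate_mean = 1, call_rate_sd = 0,
                   reproducibility_mean = 1, reproducibility_sd = 0,
                   genotyping_error_rate = 0, hg_fidelity = 1)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Hand-enumerated score-pair truth tables, written out case by case from
# the scoring semantics (0 = reference only / no band, 1 = SNP allele /
# band, 2 = both alleles / alien band size). These are the oracle; they are
# deliberately literal, not derived from the classifier's rules.
dart_truth_table <- function() {
  read.table(header = TRUE, na.strings = "NA", text = "
recipient donor status
0 0 monomorphic
0 1 polymorphic_absent_in_recipient
0 2 polymorphic_absent_in_recipient
0 NA excluded
1 0 monomorphic
1 1 monomorphic
1 2 polymorphic_codominant
1 NA excluded
2 0 monomorphic
2 1 monomorphic
2 2 polymorphic_codominant
2 NA excluded
NA 0 excluded
NA 1 excluded
NA 2 excluded
NA NA excluded
")
}

pcr_truth_table <- function() {
  read.table(header = TRUE, text = "
recipient donor status
0 0 non_amplified
1 0 non_amplified
2 0 non_amplified
0 1 polymorphic_absent_in_recipient
1 1 monomorphic
2 1 size_polymorphic
0 2 size_polymorphic
1 2 size_polymorphic
2 2 monomorphic
")
}
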