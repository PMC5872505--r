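---
title: "Typing wheat-alien chromosome introgression lines from marker score matrices"
author: "cilmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing wheat-alien chromosome introgression lines from marker score matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cilmark)
```

## The problem

Wild relatives of bread wheat (*Triticum aestivum*, 2n = 42, genomes AABBDD)
carry stress-tolerance and disease-resistance genes that breeders move into
wheat through chromosome introgression lines (CILs): disomic addition lines
(wheat plus one alien chromosome pair), arm-translocation lines (an alien
chromosome arm replacing a wheat arm), and recombination lines (a wheat
chromosome carrying a terminal alien segment created by induced
homoeologous pairing). Tracking which alien chromosome, arm or segment a
line carries needs molecular markers that distinguish the alien genome from
wheat. `cilmark` implements the marker-side analysis of such a program for
a panel built around the perennial wild rye *Leymus racemosus* (2n = 4x =
28, fourteen chromosomes): from raw PCR band scores and DArT-seq SNP score
matrices to polymorphic-marker catalogues, chromosome- and arm-specific
marker sets, homoeologous-group assignments, recombinant-fragment maps,
cross-species transferability summaries, and a UPGMA species dendrogram.

## Score semantics and the two platforms

Both platforms produce markers × genotypes integer matrices:

* **DArT-seq SNPs** ("one-row" export): `0` = reference (wheat) allele
  only, `1` = SNP allele only, `2` = both alleles; `-` = missing call.
  Each marker carries a call rate, a reproducibility, and — where the
  platform could place the SNP — a corresponding wheat chromosome (1A–7D)
  and physical position.
* **PCR bands**: `0` = no band, `1` = band; for the few size-polymorphic
  markers `1` is the wheat band size and `2` the introgression-line band
  size. PCR scores have no missing state.

A score of 1 **or** 2 counts as "positive" (the genotype shows the alien
allele or band): an introgression line carries both the wheat and the alien
complement, so a codominant `2` is evidence of alien presence. A missing
call is never evidence in either direction.

## The pipeline stage by stage

**Quality filtering** (`filter_quality`) retains DArT markers with call
rate ≥ 0.85 and reproducibility ≥ 0.95 (both inclusive). The call-rate cut
is the standard threshold for reliable DArT-seq SNPs; the platform does not
publish a canonical reproducibility cut, so 0.95 is the package default and
both thresholds are exposed as parameters.

**Polymorphism classification** (`classify_polymorphism`) is a pure
function of the recipient score, donor score and platform. For DArT: donor
1/2 with recipient 0 is *absent-in-recipient* polymorphism (the class that
dominates a wheat × wild-relative comparison); donor 2 with recipient 1/2
is the *codominant* class; a missing parental score excludes the marker
(polymorphism cannot be assessed — the conservative choice); everything
else is monomorphic, including markers whose donor lacks the SNP allele.
For PCR: donor 0 is non-amplified, donor 1 / recipient 0 is
presence/absence polymorphism, unequal scores involving a 2 are size
polymorphism. Statuses partition the marker set; summary percentages are
rounded half-up (`pct`), the convention used in published tables of this
kind (e.g. 12.5% prints as 13, not 12).

**Set logic over the panel** (`classify_markers`): a polymorphic marker
*locates* an alien chromosome when at least one addition line is positive;
it is *chromosome-specific* when exactly one addition line is positive.
Markers positive in several addition lines are recorded as co-amplified
with no specific label. For chromosomes with translocation lines,
chromosome-specific markers split into *short-arm*, *long-arm*, *both*
(flagged — observed when one "translocation" is really a segment of the
other), and *untransmitted-segment* markers (positive in the addition line
but neither arm); markers positive in a translocation but no addition line
are flagged as *background-interaction* polymorphisms. *CIL-based SNPs*
(`find_cil_based_snps`) are positive in ≥ 1 addition line while both
parents score 0 — polymorphisms created by the alien × background
interaction; those in exactly one line are line-specific, shared ones are
"common", counted once in the de-duplicated total but per-line in the
per-line table. "Common" means shared by two or more lines, not by all
nine: that is the only reading under which published per-line common
counts can each exceed the de-duplicated total.

**Homoeologous groups** (`assign_homoeologous_group`): wheat's 21
chromosomes form seven groups of three (A/B/D subgenomes). Each alien
chromosome is assigned to the group whose three wheat chromosomes absorb
the most correspondences of its chromosome-specific DArT markers (PCR
markers carry no positional metadata and are excluded by default). The
call is `ND` below `min_evidence = 5` corresponding markers or on a tie;
no tie-break is invented. Five separates the published single-marker
undetermined case from every determined case (hundreds of markers) by a
wide margin on both sides.

**Recombinant fragments** (`call_fragment_arm`,
`build_graphical_genotype`, `summarize_bins`): a fragment's arm is called
only when one arm's arm-specific markers are positive, the other arm has
none, and the total meets `min_arm_evidence = 3` — two positives stay
"uncertain", seven or more call cleanly, and 3 is the smallest integer
consistent with both published behaviours. Graphical genotypes order the
chromosome-specific markers that correspond to one wheat chromosome by
physical position and render each line as an alien / recipient / missing
track; bins are maximal alien runs whose boundaries are marker positions
(marker resolution is the only evidence, so nothing is interpolated, and a
missing call breaks a run rather than being imputed). Tracks export as a
0-based half-open BED-like TSV.

**Transferability and the species tree** (`summarize_transferability`,
`upgma`): per species, amplified counts split by marker source (genomic
DNA vs RNA-seq derived), the percent of the panel amplified, and — among
amplified markers — the percent polymorphic against wheat. Markers
amplified in at least two species form the co-amplified set; their binary
profiles feed a simple-matching distance (both shared presences and shared
absences are informative, matching how the bands were scored; Jaccard is
available by flag) and UPGMA clustering. UPGMA is implemented in the
package because its determinism matters for testing: inter-cluster
distance is the arithmetic mean over all cross pairs, node height is half
the merge distance, and ties break by the lexicographic order of cluster
labels, so the tree is independent of input order. Tests cross-check it
against `stats::hclust(method = "average")` through cophenetic distances
and verify ultrametricity to 1e-9 of tree height.

## The synthetic panel

No raw marker matrix is distributed for the study design this package
follows, so `simulate_panel()` generates a structural twin with full
ground truth; it is first-class, tested code, and every pipeline stage is
validated against it. Defaults mirror the study conditions:

| parameter | default | what it emulates |
|---|---|---|
| `n_donor_chromosomes` | 14 | the tetraploid donor's chromosome count |
| `additions` | 9 labels | chromosomes represented as addition lines |
| `translocations` | I, J, N | chromosomes with short+long arm lines |
| `recombinations` | 7 N-lines | terminal fragments, breakpoints 0.012–0.98 of an arm (one near-empty line that stays "uncertain", two near-whole-arm lines, the rest intermediate) |
| `markers_per_chromosome` | 800 | a filtered DArT-seq SNP panel (~11k markers) |
| `frac_monomorphic` | 0.30 | markers shared between the two genomes |
| `frac_codominant` | 0.011 | the small donor-codominant SNP class |
| `interaction_snp_rate` | 0.13 | CIL-based SNPs per base marker |
| `call_rate_mean/sd` | 0.95 / 0.04 | per-marker missingness |
| `hg_fidelity` | 0.9 | markers whose wheat correspondence points into the true homoeologous group |
| `chrom_length_bp` | 8e8 | wheat-scale coordinates (positions uniform; short arm below 0.45 of the length) |

Addition lines carry every marker of their chromosome, translocation lines
one arm, recombination lines only the markers inside a terminal segment;
interaction SNPs are positive in one or a few lines and absent in both
parents; genotyping error flips cells at a configurable rate (0 by
default). The species screen evolves marker loss along a Newick hierarchy
whose edge lengths are loss probabilities, conditioned on retention in the
donor (the panel is donor-pre-screened by construction).

What the generator does **not** emulate: linkage between markers beyond
shared chromosome membership, segregation distortion, platform-specific
allele-calling error structure, paralogous amplification, or any sequence-
level process. Passing the recovery tests therefore shows the set logic
and bookkeeping are correct, not that real panels are free of those
complications.

The repository's headline property test generates a noise-free panel
(~10^4 markers × 25 genotypes, no missingness, no genotyping error,
faithful correspondences) and requires exact recovery of every chromosome
assignment, arm assignment, homoeologous group, and breakpoint interval —
and, at three increasing genotyping-error rates under fixed seeds, that
chromosome-assignment accuracy never improves with more noise.

## Numerical and design choices

* Percentages: half-up integer rounding (`floor(x + 0.5)`); a zero
  denominator reports 0 (flagged where it matters).
* Call rate and reproducibility accept fraction (0–1) or percent (0–100)
  dialects, auto-detected per column by `max > 1`, stored as fractions.
* Column matching between manifests and score files is exact and
  case-sensitive; parsing never coerces: an unknown score symbol names its
  row and column and stops.
* Quality filtering precedes classification; position availability is
  checked only by the operations that need positions (graphical
  genotyping), so unpositioned markers still contribute to location,
  specificity and arm logic.
* A marker with a missing recipient score can be neither polymorphic nor
  CIL-based; a missing donor score still allows CIL-based status (the
  definition needs donor *absence*, and a missing donor call is treated as
  compatible with absence only where the recipient is confidently 0).
* Desk-scale reproduction: the bundled reference tables
  (`reference_table()`) carry the published per-line counts this workflow
  re-derives its summary logic from. In the source publication's extracted
  tables a few cells are internally inconsistent (one species row's three
  polymorphism percentages cannot be produced by any amplified-count
  decomposition; one DNA-percent cell is off by one from the only
  consistent count) — those cells are stored as printed but excluded from
  identity checks, and digit-grouping ambiguities in two correspondence
  rows affect only cells that no downstream quantity consumes.

## Known limitations

* Arm calls assume the two translocation lines faithfully partition the
  chromosome; a translocation that is biologically a segment of the other
  arm shows up as an excess of `both`-arm markers, which the classifier
  flags but does not reinterpret.
* Homoeologous-group evidence uses correspondence labels as the platform
  provides them; no sequence-level homology search is performed.
* UPGMA assumes clock-like divergence; for markedly non-ultrametric
  profile distances the dendrogram is a clustering summary, not a
  phylogeny estimate.
* The bin summary reports marker support, not physical breakpoint
  likelihoods; with sparse marker coverage small fragments legitimately
  go undetected (the panel's near-empty recombination line is the
  designed example).
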