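Package: cilmark
Title: Marker Classification and Introgression Typing for Wheat-Alien
    Chromosome Introgression Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing wheat-alien chromosome introgression
    lines (CILs) from PCR band scores and DArT-seq SNP score matrices.
    Implements quality filtering and polymorphism classification of markers
    against the recipient and donor parents, alien-chromosome location and
    chromosome-/arm-specific marker assignment across panels of disomic
    addition, arm-translocation and recombination lines, homoeologous-group
    inference by marker correspondence counting, graphical genotyping of
    recombinant fragments along recipient-chromosome coordinates,
    cross-species marker transferability summaries, UPGMA clustering of
    binary co-amplification profiles, and a seeded synthetic-panel generator
    with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
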