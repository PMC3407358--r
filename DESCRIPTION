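Package: nidotax
Title: Genetics-Based Species Demarcation for Nidovirus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genetics-based taxonomic demarcation of nidoviruses
    and similar RNA virus groups. Annotates open reading frames, relative
    reading frames, ribosomal-frameshift slippery sites and
    transcription-regulating-sequence motifs on genome sequences; builds
    per-ORF nucleotide and amino-acid identity tables between genome pairs
    via global alignment; concatenates conserved replicase-domain amino-acid
    alignments (e.g. 3CLpro, RdRp, HEL1, ExoN, OMT) and computes pairwise
    evolutionary distances under p-distance, Poisson and Gamma-Poisson
    models; derives species/genus demarcation thresholds by minimising a
    single-linkage clustering cost over candidate cutoffs; and classifies
    virus pairs against intra-species divergence. Includes a seeded
    hierarchical-taxonomy sequence simulator that provides ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
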