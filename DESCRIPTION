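Package: gpsmeth
Title: Guide Positioning Sequencing: Simulation, Guided Alignment and
    Allele-Specific Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for guide positioning sequencing (GPS) bisulfite
    libraries, in which T4 DNA polymerase replaces the 3'-terminal 36-150
    nucleotides of each fragment with 5-methyl-dCTP so that Read2 retains
    an unconverted "anchor" prefix while Read1 carries ordinary bisulfite
    signal. Provides a GPS library simulator with per-read ground truth
    (fragmentation, T4 excision and 5mC patching, bisulfite conversion,
    unmethylated lambda spike-in, sequencing error), quality filtering and
    exact duplicate removal, detection of the T4 treatment boundary on
    Read2 (last non-CpG G rule), anchor placement by exact k-mer seeding,
    guided positioning of Read1 by Smith-Waterman local alignment with
    bisulfite-aware scoring within 1 kb of each anchor, treatment-consistent
    read trimming, per-cytosine methylation calling, spike-in conversion
    efficiency estimation, candidate variant calling from protected Read2
    segments, and allele-specific methylation detection by contrasting
    methylation between allele groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
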