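Package: switchjoint
Title: Class-Switch-Recombination Junction Analysis from Long-Read and
    HTGTS Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls and classifies class switch recombination (CSR)
    junctions at immunoglobulin switch regions. Provides a genomic locus
    model for switch assays (primers, S regions, regions of interest,
    productive-length thresholds), split-read breakpoint calling from
    long-range PCR amplicon reads (PacBio CCS) with unique-junction
    deduplication at a sequencing-depth floor and resected-joint
    classification, HTGTS-style junction-table profiling (deletional
    versus inversional orientation, acceptor-region assignment, binned
    distributions), DNA repair signatures at junctions (microhomology,
    untemplated insertions, direct joints, microhomology-usage
    landscapes), V(D)J Sanger-junction decomposition into resection,
    microhomology and insertion, and two-sided Fisher's exact contrasts
    for metaphase aberration count tables. Includes a seeded synthetic
    CSR-event simulator that generates a miniature switch locus, ground
    truth event tables, amplicon reads, HTGTS junction tables and V(D)J
    junction sequences for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
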