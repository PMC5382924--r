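Package: crisprleader
Title: Mining and Motif Classification of Type II-A CRISPR Leader-Repeat
    Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies complete type II-A CRISPR-Cas loci (cas9, cas1,
    cas2, csn2) in annotated bacterial genomes, locates the repeat-spacer
    array downstream of csn2 with a seed-and-extend tandem-repeat
    detector, extracts the leader-repeat junction, and classifies each
    locus into one of three conserved 3' leader-end motif groups
    (ATTTGAG, CTRCGAG, or a short CG end). Includes global pairwise and
    progressive multiple alignment for short DNA, alignment-free k-mer
    distances for Cas proteins, neighbor-joining tree construction with
    clade cutting, position-frequency conservation profiles with
    information content and IUPAC consensus calling, concordance
    statistics between tree clades and motif groups, and a seeded
    synthetic-genome simulator with planted loci for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
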