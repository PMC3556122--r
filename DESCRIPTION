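Package: iapmeth
Title: Phylogeny-Guided Discovery of Variably Methylated IAP LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and validating candidate metastable epialleles
    among murine intracisternal A particle (IAP) long terminal repeats (LTRs).
    Parses RepeatMasker annotations and extracts LTR elements with flanking
    sequence from a genome; builds neighbor-joining trees under the Jukes-Cantor
    model and partitions them into clades scored by divergence from a family
    consensus; designs combined bisulfite restriction analysis (CoBRA) assays by
    in-silico bisulfite conversion, methylation-dependent restriction-site
    detection and junction-spanning primer design; converts gel band intensities
    to percent methylation with limit-of-detection handling; and summarises
    mice-by-loci methylation matrices with clade-level ANOVA and Tukey-adjusted
    contrasts. A seeded simulator generates toy genomes with planted
    clade-structured LTR insertions and matching methylation matrices so the
    whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
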