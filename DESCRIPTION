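Package: dmscreen
Title: Deep Mutational Scanning Pipeline for Codon-Saturation Resistance Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deep mutational scanning (DMS) of an open reading frame:
    design of codon-saturation variant libraries under restriction-site and
    codon-distance constraints, synonymous recoding of CRISPR PAM sites in
    rescue constructs, codon-level variant calling and tallying from paired
    amplicon reads, pooled-screen survival scoring (T0-normalized log2 fold
    changes, z-scores, standard-deviation hit calls), and structural
    classification of resistance hits into active-site, homodimer-interface
    and partner-interface categories. Includes a fully seeded synthetic-screen
    simulator (library representation, rule-based selection, multinomial
    sequencing counts, paired FASTQ reads) that provides ground truth for
    every downstream stage. Developed around a PDE3A/DNMDP resistance screen
    but applicable to any single-ORF saturation library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
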