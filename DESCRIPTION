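Package: srwalk
Title: Selective Recursive Local Assembly of Homologous Gene Regions
    from Short Reads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Targeted local assembly of a gene locus from unassembled
    short-read libraries by in silico chromosome walking. Starting from a
    protein or DNA probe from a related species, reads sharing significant
    exact matches with the probe (in translated space for protein probes)
    are recruited, locally assembled with a de Bruijn unitig assembler run
    as a k-mer sweep, and the resulting contigs are used as queries for
    further recursive rounds of read recruitment until a contig covering
    the probe is recovered or stopping criteria fire. Includes spliced
    alignment of the probe to contigs, DUST low-complexity masking,
    periodic cleaning of non-matching contigs and reads, retirement of
    over-long contigs, and a paired-end read simulator with planted
    multi-exon genes so the whole workflow can be exercised on synthetic
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
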