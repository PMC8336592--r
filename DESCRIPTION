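Package: vgsieve
Title: Variant Selection for Variation Graphs with Path-Preservation Guarantees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects a reduced subset of variants (SNPs, insertions, deletions)
    for a pangenome variation graph so that every path of length alpha in the
    complete graph still maps to the reduced graph within an error budget delta
    (Hamming distance for SNP-only graphs, edit distance otherwise). Provides an
    optimal sweep-line greedy minimising variant-containing loci, an optimal
    interval-constraint programme minimising total variants (solved exactly via
    a totally unimodular min-cost-flow equivalent), conservative greedy and
    branch-and-bound heuristics for graphs with indels and structural variants,
    a path-enumeration oracle that certifies (alpha, delta)-compatibility, and
    seeded simulators for SNP, SNP+indel and SV variant catalogues. Reads and
    writes FASTA/VCF and ships a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    optparse,
    vcfR,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
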