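Package: orthoprune
Title: Tree-Based Homology Refinement and Orthology Inference for
    Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds phylogenomic data sets from transcriptomes and
    low-coverage genomes using gene trees for both homology and orthology
    assignment. Filters all-by-all similarity searches by hit fraction and
    E value, prepares Markov-cluster (MCL) input and parses its output,
    cleans homolog trees by cutting long internal branches, trimming
    spurious long tips and masking monophyletic or paraphyletic isoform
    tips, and extracts ortholog trees by four strategies: maximum
    inclusion (MI), rooted ingroup-clade duplication pruning (RT),
    monophyletic-outgroup rooting (MO), and strict one-to-one filtering
    (1to1). Includes supermatrix assembly with per-locus partitions and
    occupancy statistics, locus-intact jackknife resampling, bipartition
    support summaries, and a synthetic gene-family simulator with known
    duplication histories and injected isoform and misassembly artifacts
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.0),
    Biostrings,
    IRanges,
    data.table,
    phytools,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
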