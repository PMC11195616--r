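Package: islandbreak
Title: Genomic Island Detection from Synteny Breaks in Closely Related Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic islands as breaks in synteny between closely
    related annotated bacterial genomes. Orthologs are inferred by filtered
    best-reciprocal-hit protein comparison with synteny-based resolution of
    ambiguous hits, chained into gap-tolerant colinear synteny blocks, and
    regions between blocks that are consecutive in both genomes are reported
    as candidate genomic islands. Each island is scored with features
    suggestive of specialized-metabolite biosynthetic gene clusters: CDS
    counts, genes without orthologs, paralogy, tRNA proximity, GC deviation
    and annotation keywords. Islands can be filtered, ranked with user
    weights, and summarized with gene-order-conservation profiles; islands
    recurring at the same anchored chromosomal location across a multi-genome
    set are grouped into integration hotspots. A seeded simulator generates
    annotated genome pairs with implanted islands and full truth tables for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
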