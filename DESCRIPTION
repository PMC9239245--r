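Package: strainpan
Title: Pangenome, Variant, and Mobile-Element Comparison for Closely Related
    Bacterial Strain Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative genomics for panels of closely related bacterial
    strains, modelled on the freshwater cyanobacterium Synechococcus
    elongatus. Builds a pangenome from reciprocal-best-hit ortholog groups,
    calls SNPs and indels inside group alignments with codon-aware effect
    classification, computes fragment-based average nucleotide identity and
    reciprocal-best-hit average amino acid identity, detects integrated
    prophages anchored at tRNA genes by their exact terminal att-site
    duplications, scans HIP1 octamers, detects inversions and plasmid
    fusions from unique k-mer anchors, finds CRISPR repeat-spacer arrays,
    reconciles per-strain annotations into a consensus pangenome annotation,
    and tests gene-set enrichment with fold-enrichment statistics,
    two-sided Fisher exact tests and Benjamini-Hochberg FDR control. A
    synthetic-genome generator with a machine-readable truth log supports
    end-to-end validation of every detector.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
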