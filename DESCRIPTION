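Package: anchormap
Title: Outbred F1 Linkage Mapping and Draft Genome Anchoring from Targeted Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building linkage maps from target-capture genotyping of an
    outbred F1 (pseudo-testcross) population and for anchoring a fragmented draft
    genome assembly onto the map. Implements a genotype quality-control cascade
    (depth and allele-balance call replacement, call-rate, Mendelian-consistency
    and segregation-distortion filters), two-point recombination-fraction and LOD
    estimation by expectation-maximization over unknown parental phases,
    LOD-threshold grouping with map selection against a reference map, marker
    binning, ordering and Haldane cM positioning, contig and scaffold placement
    with discordance detection, microsatellite-primer placement rules on
    fragmented assemblies, and RNA-seq variant classification with gene-set
    reconciliation. A synthetic-data module simulates a two-parent cross with
    mixed segregation types, depth-sampled allele counts, genotyping error,
    missingness, segregation distortion and repeat-duplicated contigs so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
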