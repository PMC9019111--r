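Package: kdrhap
Title: Haplotype Analysis of Target-Site Insecticide Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing target-site pyrethroid resistance variation
    in the mosquito voltage-gated sodium channel (Vgsc) gene from phased
    genotype data: strand-aware codon-effect annotation of SNPs against a
    GFF3 gene model, population allele frequencies with a maximum-frequency
    filter, Lewontin's D' linkage disequilibrium between resistance alleles,
    nucleotide diversity and piN/piS on haplotype subsets, a Dirichlet
    Monte-Carlo heterozygote-excess test, haplotype-group discovery by
    hierarchical clustering and median-joining networks, selection scans
    (extended haplotype homozygosity, moving-window haplotype homozygosity,
    pairwise shared-haplotype lengths), and decision-tree design of
    surveillance SNP panels. A seeded synthetic-cohort generator plants
    selective-sweep haplotype groups with known ground truth so that the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
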