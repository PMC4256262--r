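Package: methcross
Title: Genetic Analysis of CpG Methylation in Inbred Crosses and
    Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for the genetic dissection of CpG
    methylation from whole-genome bisulfite sequencing (WGBS) in
    two-strain crosses: strand-specific cytosine pileups, bisulfite
    conversion-rate estimation from unmethylated lambda spike-ins and
    non-CpG cytosines, conversion-corrected methylation calling,
    Fisher-test differential methylation with Benjamini-Hochberg FDR
    control and 500-bp region clustering, phasing of F1 reads by
    parental SNP alleles, allele-specific and parent-of-origin
    methylation detection in reciprocal crosses, single-marker
    methylation-QTL mapping with permutation significance in a
    recombinant inbred panel, heritability by intraclass correlation,
    quantitative trait methylation (phenotype) correlation after
    outlier screening, and sequence-context statistics around
    differentially methylated CpGs.  A synthetic-data module generates
    parental, reciprocal-F1 and recombinant-inbred data sets with known
    truth so every stage can be validated end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
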