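Package: consangkit
Title: Simulation and Inference of Consanguinity and Endogamy from ROH and IBD Segments
Version: 0.1.0
Authors@R: person("BiB", "Methods", email = "methods@example.org", role = c("aut", "cre"))
Description: Tools for studying consanguinity and endogamy from runs of
    homozygosity (ROH) and identity-by-descent (IBD) segments. Includes a
    pedigree/meiosis simulator for ten classes of consanguineous union, a
    sliding-window ROH caller, a neural-network classifier of parental
    relatedness with majority voting, conversion of inferred union classes
    to per-generation consanguinity rates and kinship, a coalescent model
    for the expected genomic footprint of ROH and IBD segments given an
    effective-population-size trajectory, an endogamy IBD score with
    weighted block-jackknife standard errors, and a carrier-pairing
    simulation of recessive-disease couple risk. A synthetic-data module
    generates founder haplotype panels, endogamous populations, and
    group-structured carrier tables so every stage can be exercised
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
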