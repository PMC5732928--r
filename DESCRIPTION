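Package: riverkin
Title: Conservation Genetics of Riverine Fish Broodstock
Version: 0.1.0
Authors@R: person("Ana", "Moreira", email = "ana.moreira@example.org",
                  role = c("aut", "cre"))
Description: Population-genetic analysis of small, fragmented riverine fish
    populations and of captive broodstock derived from them. Provides
    microsatellite diversity statistics (allele counts, rarefied allelic
    richness, observed and unbiased expected heterozygosity, F_IS), exact
    Hardy-Weinberg and linkage-disequilibrium tests, Jost's D_EST with
    bootstrap significance, AMOVA phi_ST on haplotype alignments,
    heterozygosity-excess bottleneck tests under IAM/SMM/TPM mutation models,
    DAPC and neighbour-joining individual clustering, mitochondrial summary
    statistics with Fu's Fs and R2 neutrality tests and median-joining
    haplotype networks, pairwise relatedness estimators (moment and dyadic
    maximum-likelihood), and a kinship-based mating advisor for captive
    breeding. Includes coalescent and pedigree simulators that generate
    synthetic genotype and sequence data with the statistical structure the
    analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    MASS,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
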