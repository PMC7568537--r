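Package: cavepop
Title: Population-Genomic Inference for Island-Like Cave Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for RAD-seq population genomics of strongly subdivided,
    island-like populations such as obligate cave dwellers. Provides a
    Wright-Fisher island-model simulator with read-level genotype-likelihood
    emulation; hard-call and genotype-likelihood SNP filtering (depth,
    call rate, singletons, exact Hardy-Weinberg heterozygote-excess,
    SNP likelihood-ratio and heterozygote-majority paralog screens);
    identity-by-state distance matrices with hierarchical clustering,
    classical multidimensional scaling and BIC-based cluster-number
    selection; admixture ancestry estimation by expectation-maximization
    from hard calls or genotype likelihoods; pairwise differentiation
    (Weir-Cockerham theta, Reynolds-style weighted and unweighted FST,
    dXY); nucleotide diversity from hard calls and from folded site
    frequency spectra estimated by EM over genotype likelihoods; effective
    population size and island-model migration-rate inversion; and an
    end-to-end pipeline producing report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    ape,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
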