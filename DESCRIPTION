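Package: plastcomp
Title: Comparative Chloroplast Genome Structure, Repeats and Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of circular quadripartite
    chloroplast genomes: detection of the LSC/IRb/SSC/IRa partition and
    gene-to-junction distances, dispersed direct/reverse/palindromic repeat
    and microsatellite (SSR) detection, pairwise substitution and indel
    event counting with S/I ratios and indel length spectra, screening of
    divergence hotspot markers by the proportion-of-mutational-events
    statistic, partitioned divergence ratios, and Fitch parsimony mapping
    of binary indel characters onto a phylogeny.  Includes a synthetic
    plastome-evolution simulator that generates annotated quadripartite
    genomes and evolves them along a tree with region-specific rates,
    duplication-biased indels and concerted evolution of the inverted
    repeats, emitting ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
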