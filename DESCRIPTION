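Package: morphdrift
Title: Drift Versus Selection Tests for Color-Morph Sorting from mtDNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to ask whether complete phenotypic sorting of color
    morphs is plausible under neutral genetic drift. Implements the
    Slatkin-Maddison s statistic (minimum deme-state transitions on a gene
    tree, exact on multifurcating trees), a structured-coalescent simulator
    of gene trees within a morph/population tree, branch-length tuning at a
    lower-tail quantile criterion, nuclear rescaling of mitochondrial branch
    lengths, and the resulting incomplete-lineage-sorting selection test.
    Also provides mitochondrial summary statistics (segregating sites,
    nucleotide diversity, Tajima's D with coalescent significance, pairwise
    Phi-st with permutation tests), minimum spanning haplotype networks,
    binomial-GLM analysis of deviance for reciprocal-translocation predation
    experiments, and coalescent generators for synthetic alignments and
    predation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
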