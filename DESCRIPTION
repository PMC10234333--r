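Package: stutzpan
Title: Genomospecies Delineation, Pan-Genome Analysis and 16S Signature
    Screening for Bacterial Species Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for delineating and screening
    bacterial species within taxonomically tangled complexes such as the
    Stutzerimonas (former Pseudomonas stutzeri) group. Implements
    fragment-based average nucleotide identity (ANIb) with bidirectional
    averaging and 95 percent genomospecies clustering, ortholog clustering
    from proteomes under the 70/70 rule with three algorithms (bidirectional
    best hit, COG triangles, Markov clustering), strict consensus
    single-copy core genomes, pan-genome compartments and in-group
    exclusive pan-genes, gene-discovery curve sampling with Tettelin and
    Willenbrock exponential fits and extrapolation, Jukes-Cantor
    neighbor-joining phylogenetics with bootstrap supports and
    Gblocks-style alignment trimming, and a two-step 16S rRNA
    signature-nucleotide screening classifier. Ships synthetic-data
    generators with serialized ground truth so every stage can be exercised
    end-to-end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    minpack.lm,
    jsonlite,
    data.table,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
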