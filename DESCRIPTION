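Package: clonetracer
Title: Clonal Evolution Analysis of Single-Cell Targeted Genotyping Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reconstructs tumor clonal evolution at single-cell,
    single-variant resolution from targeted genotyping panels. Takes a
    cells-by-sites ternary genotype matrix (mutant / reference / missing)
    with site and cell metadata, performs quality control (allele-dropout
    estimation from heterozygous germline control sites, mutated-cell
    fraction versus bulk variant-allele-frequency concordance,
    paratumor-based germline and artifact filtering), groups cells into
    clones by their mutation combinations, reconstructs a perfect-phylogeny
    clone tree with virtual (unobserved) ancestor nodes and per-edge
    acquired mutations, classifies mutations as trunk, tissue-private
    clonal, tissue-shared or subclonal across primary and metastatic
    tissues, tabulates per-branch pyrimidine-reference substitution
    spectra, and builds a maximum-parsimony tree of single cells with
    Fitch scoring (exhaustive for small inputs, nearest-neighbor
    interchange otherwise). A synthetic-data generator with an explicit
    allele-dropout / false-positive / missingness noise model provides
    ground-truth datasets for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
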