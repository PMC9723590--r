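Package: phylosym
Title: Phylosymbiosis Testing for Host-Associated Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing phylosymbiosis -- the pattern in which
    host-associated microbial communities recapitulate the host phylogeny --
    from amplicon sequence variant (ASV) count tables. Implements the
    complete workflow: quality filtering (control-ASV removal, minimum read
    depth), rarefaction, alpha diversity (Faith's phylogenetic diversity),
    beta diversity (Bray-Curtis, Jaccard, unweighted and weighted UniFrac),
    species-level aggregation (mean-ceiling averaging and random sample
    picking), UPGMA dendrograms, normalized Robinson-Foulds congruence with
    a randomized-tree null, Mantel tests against patristic distances,
    phylogenetic signal (Blomberg's K, Pagel's lambda) on principal
    coordinates, phylogenetic generalized least squares trait regression,
    PERMANOVA and dispersion homogeneity checks, plus a synthetic community
    generator with controllable phylosymbiosis strength and clade-age
    stratified diet effects for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.0),
    vegan (>= 2.6),
    phytools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    picante,
    nlme,
    yaml,
    withr,
    jsonlite
Config/testthat/edition: 3
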