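Package: chemotax
Title: Chemotype Clustering and Genetic Concordance for LC/MS Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing cryptic species through secondary-metabolite
    fingerprints. Converts per-individual LC/MS acquisitions into
    baseline-corrected total chromatogram mass (TCM) spectra binned at nominal
    (unit) mass, clusters individuals by Pearson correlation of spectral shape
    with a similarity-threshold dendrogram cut, screens chemo-group/phylogroup
    disagreements with principal component analysis, and cross-tabulates
    chemical groups against genetic phylogroups (contingency tables, mapping
    cardinality, adjusted Rand index). Includes genetic bookkeeping for
    multilocus work (concatenation with a minimum-gene inclusion rule, IUPAC
    ambiguity coding of heterozygous sites, MCMC posterior-sample accounting,
    distance-threshold phylogroup assignment) and a synthetic cohort generator
    emulating chemotype-structured LC/MS data with genetic label scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    mclust,
    mzR,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
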