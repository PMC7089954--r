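Package: hapsentinel
Title: Replicated Association, Ancestral Haplotype Reconstruction, and
    LD-Based Sentinel Variant Selection for Familial Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting a densely genotyped risk locus in
    case-control studies of familial disease. Implements replicated
    single-variant association scans under additive logistic models with a
    penalized-likelihood fallback for separated data, two-study concordance
    filtering, sliding-window haplotype association over phased genotypes
    with assembly of ancestral risk-altering haplotype models, the RISSc
    recursive linkage-disequilibrium binning algorithm for sentinel variant
    selection, bootstrap optimism-corrected AUC risk prediction, and
    genotype modifier tests of age at diagnosis and clinical severity. A
    bundled simulator generates phased two-study case-control datasets with
    mosaic-founder linkage disequilibrium and planted risk or protective
    haplotypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
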