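Package: diallelqg
Title: Quantitative Genetics of Half-Diallel Forest Progeny Trials with
    Pedigree and Genomic Relationship Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for additive-dominance quantitative genetic analysis of
    full-sib progeny trials laid out as incomplete half-diallels, as used in
    hardwood (e.g. Eucalyptus) breeding programs. Builds pedigree numerator
    (A) and dominance (D) relationship matrices, marker-based additive and
    dominance genomic relationship matrices from co-dominant SNPs (VanRaden)
    and dominant presence/absence markers, with Vitezica and Su dominance
    parameterizations; estimates variance components of individual-tree
    mixed models by average-information REML with EM fallback, including a
    bivariate additive model for genetic correlations; re-parameterizes fits
    into narrow- and broad-sense heritabilities with delta-method standard
    errors; runs marker-subsampling stability analyses; and calibrates
    near-infrared spectra to wood traits via Kennard-Stone subset selection
    and partial least squares with external validation. A synthetic
    half-diallel population generator (genotypes, Mendelian offspring,
    phenotypes, dominant markers, spectra) makes the whole pipeline testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
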