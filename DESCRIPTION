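Package: micropls
Title: Compositional Multivariate Analysis and Sparse PLS-DA for
    Microbiome Count Data
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multivariate analysis of OTU count tables treated as
    compositional data. Provides prefiltering of samples and rare OTUs,
    total sum scaling with centred and isometric log-ratio transforms,
    cumulative sum scaling, within-subject variance decomposition for
    repeated-measures designs, principal component and principal
    coordinate ordination, and multiclass sparse partial least squares
    discriminant analysis with cross-validated selection of the number
    of OTUs per component. Includes contribution tables, GraPhlAn
    annotation export, confidence ellipses, and a Dirichlet-multinomial
    simulator of sparse repeated-measures microbiome counts with known
    discriminative OTUs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    MASS,
    optparse
Config/testthat/edition: 3
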