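Package: afenm
Title: Elastic Network Models from AlphaFold Confidence Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts AlphaFold2 per-residue confidence (pLDDT) and
    predicted aligned error (PAE) matrices into elastic network models
    with physically motivated, PAE-scaled force constants
    (k = kB*T/PAE^2), writes them as GROMACS topology includes, and
    provides the companion analysis toolbox: Calpha distance-fluctuation
    statistics (sigma_d matrices, sigma_d,n flexibility profiles, RMSF,
    radius of gyration), score-versus-dynamics correlation and
    threshold-sweep analyses, ensemble comparison by PCA projection and
    multivariate Kullback-Leibler divergence, and a synthetic-data
    generator (toy chains, score fields, normal-mode harmonic ensembles)
    that makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, bio3d
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'afenm-package.R'
    'utils.R'
    'afio.R'
    'dynmetrics.R'
    'enm.R'
    'enscomp.R'
    'scorecorr.R'
    'synth.R'
    'topo.R'
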