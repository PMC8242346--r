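Package: integrinscape
Title: Pan-Cancer Multi-Omics Characterization of Integrin Subunit Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for pan-cancer characterization of the 30
    integrin subunit genes (ITGs) across tumor/normal cohorts: differential
    expression screening with gene-set enrichment, attribution of
    dysregulation to copy-number or DNA-methylation drivers by composite
    alteration-fraction and expression-correlation criteria, nonsynonymous
    mutation landscapes with six-category substitution spectra,
    horizon-restricted overall-survival screening via minimum-log-rank-p
    expression cutpoints, multivariate Cox risk models over prognostic genes
    and TNM staging indexes, and clinical covariate associations. A bundled
    synthetic multi-omics cohort generator with machine-readable truth tables
    makes every stage testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
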