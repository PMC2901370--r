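Package: washhook
Title: Hook Calibration of PM/MM Microarrays with Post-Hybridization Washing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probe-level analysis of GeneChip-type PM/MM microarrays that
    explicitly models post-hybridization washing. Implements the two-species
    Langmuir adsorption isotherm extended by survival ('washing') functions,
    estimators of probe-level washing kinetics from multi-timepoint wash
    series, the hook (Delta-versus-Sigma) analysis with and without explicit
    washing terms, power-law kinetics of the hook summary parameters and
    their inversion into per-mode washing exponents, positional nucleotide
    sensitivity profiles and their washing difference profiles, and a
    washing-corrected calibration of probe intensities into specific binding
    strengths. A synthetic chip simulator with planted physical truth
    supports validation of every analysis path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
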