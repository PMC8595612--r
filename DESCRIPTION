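Package: redoxkin
Title: Kinetics of Peroxidase Reactions with Tryptophan-Derived Hydroperoxides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Estimation of rate constants and binding constants for reactions of
    hydroperoxides (hydrogen peroxide and tryptophan-derived epimeric
    hydroperoxides) with thiol and selenium peroxidases. Implements
    pseudo-first-order analysis of gel-densitometry monomer-decay time courses,
    Dalziel-coefficient analysis of NADPH-coupled glutathione peroxidase
    progression curves, initial-rate and competition-kinetics inversion,
    deterministic mass-action simulation of hydrogen peroxide partitioning
    networks, dissociation-constant calculation from native mass-spectrometry
    peak areas, spectrophotometric assay arithmetic, and seeded synthetic-data
    generators that emulate each assay for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
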