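Package: stackmap
Title: Multiscale Neutron Scattering Analysis of Self-Assembling
    Beta-Hairpin Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrated small- and wide-angle neutron scattering (SANS/WANS)
    analysis of stacked beta-hairpin peptide assemblies. Provides a composite
    small-angle intensity model (elliptical-cylinder form factor with a
    screened-Coulomb structure factor, two Gaussian peaks, a low-Q power law
    and a flat background) with a staged fitting procedure and geometric
    interpretation of the fitted parameters; total-scattering theory utilities
    (momentum-transfer geometry, Bragg distances, partial structure factors
    from radial distribution functions, isotopic-contrast weighting with
    exchangeable hydrogens); a rigid-body Monte Carlo stack builder and box
    solvator; per-site hydration-shell analysis yielding a hydrogen-bonding
    index from site-water RDF first-peak positions; and synthetic-data
    generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
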