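Package: sheetvoid
Title: Sheet-and-Void Porous-Media Models of Brain Interstitial Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic geometry and Monte Carlo diffusion tools for
    sheet-and-void models of the brain interstitial space treated as an
    unconsolidated porous medium. Implements the closed-form relations
    linking porosity, sheet width, cell size and void size for uniform
    cubic-lattice, corner-cubic-void (CCV) and edge-tunnel-void (ETV)
    cell geometries; a reflecting Brownian random-walk simulator that
    measures geometrical tortuosity from point-source diffusion via the
    mean-squared displacement; polynomial fitting and inversion of the
    tortuosity-versus-void-ratio relation; and the two-state
    (asleep/awake) porosity inference built on the CCV model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
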