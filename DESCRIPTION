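Package: carotidwk
Title: Analytical Windkessel Outlet Boundary Conditions for Carotid Artery Haemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates three-element Windkessel (RCR) outlet boundary
    conditions for carotid-artery computational fluid dynamics from the
    geometry of the downstream cerebral vasculature.  Provides closed-form
    Poiseuille hydraulic resistance and elastic-tube compliance for vessel
    segments, an electrical-analog series/parallel reduction algebra for
    lumped vascular networks, a bundled 38-segment carotid atlas (internal
    and external carotid trees with named reduction recipes and a
    printed-versus-recomputed discrepancy report), and a 0D transient
    simulator of RCR outlets with multi-outlet flow-split prediction and
    periodic steady-state detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
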