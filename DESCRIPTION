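Package: pacefit
Title: Recovering Ionic Conductances from Spontaneous Cardiac Action Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating whole-cell ionic conductance scaling factors
    from spontaneous cardiac action-potential waveforms, aimed at the
    heterogeneous electrical phenotypes of immature (hiPSC-derived)
    cardiomyocytes. Provides a compact spontaneously active membrane-excitation
    model (eleven-current roster with Hodgkin-Huxley gating, five-compartment
    calcium bookkeeping and slow Na/Ca homeostasis feedback on the Na/K pump
    and Na-Ca exchanger), a mean-squared-error objective between
    upstroke-aligned action-potential cycles, a base-point/new-point Pattern
    Search optimizer with a multi-run randomized-restart driver, global
    MSE-landscape identifiability mapping, and post-hoc principal-component
    and complementary-plane analyses of converged parameter ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
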