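Package: arbriver
Title: Stochastic Reactive-Transport Modelling of Antibiotic Resistance in Rivers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coupled deterministic and stochastic one-dimensional
    reactive-transport model of a fluoroquinolone antibiotic and
    fluoroquinolone-resistant bacteria in a polluted river reach (water
    column plus active sediment layer). Implements advection-dispersion
    transport with settling, resuspension and sediment-water diffusion
    exchange; Monod growth with antibiotic inhibition, metal inhibition
    and resistance fitness costs; plasmid conjugation and segregation;
    and an Euler-Maruyama integrator whose noise terms follow the
    Poisson diffusion approximation (variance of each process increment
    equals its deterministic rate). Includes a one-at-a-time parameter
    sensitivity harness, a multi-generation stochastic ensemble
    experiment comparing demographic, environmental and anthropogenic
    noise, scenario JSON input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
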