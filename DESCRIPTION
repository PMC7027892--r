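Package: hybridgrowth
Title: Hybrid Logistic-Monod Cell Growth Kinetics for Batch and CSTR Culture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Unstructured kinetic modelling of microbial growth with the
    Monod, Logistic and hybrid Logistic-Monod specific growth-rate laws.
    Provides closed-form (explicit or implicit) analytical solutions for
    batch culture, an independent adaptive Runge-Kutta oracle for
    validating them, closed-form chemostat (CSTR) steady states with
    washout and productivity-optimal dilution rates, a synthetic
    time-course generator, and weighted nonlinear least-squares parameter
    estimation, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
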