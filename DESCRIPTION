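Package: lipbpk
Title: Physiologically Based Pharmacokinetic Model of Lithium in Pregnancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Flow-limited, eight-compartment physiologically based
    pharmacokinetic (PBPK) model of lithium disposition in a pregnant woman
    and her first-trimester fetus under oral controlled-release dosing.
    Provides a dosing-regimen engine with zero-order absorption input,
    ODE simulation to the periodic steady state (terminal profile),
    closed-form flow-balance cross-checks, and a screening procedure that
    classifies candidate regimens against the fetal exposure produced by a
    documented pathological reference regimen. Includes a command-line
    interface for simulation, summary, screening and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
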