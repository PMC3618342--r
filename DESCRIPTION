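Package: fracz
Title: Fractional-Calculus Equivalent-Circuit Models for Bioimpedance Spectroscopy
Version: 0.1.0
Authors@R:
    person("fracz", "maintainers", email = "fracz@example.org", role = c("aut", "cre"))
Description: Closed-form evaluation, simulation and complex nonlinear
    least-squares fitting of a family of fractional-order equivalent-circuit
    impedance models: the constant phase element (CPE), the Cole dispersion,
    serially linked reduced Cole elements, and their "remnant-memory"
    generalizations in which the fractional exponent acquires a partial
    Maclaurin series in the logarithm of the dimensionless frequency.  The
    package also provides a numeric embodiment of the (generalized) Weyl
    fractional derivative on truncated Fourier series, used to verify that
    the fractional circuit relations driven by a sinusoid reproduce the
    closed-form impedances, a synthetic multi-frequency bioimpedance
    acquisition generator, staged Levenberg-Marquardt fitting with
    mean-square-error model comparison, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
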