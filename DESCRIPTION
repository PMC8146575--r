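Package: kmfinite
Title: Finite-Time Corrected Kramers-Moyal Coefficient Estimation for
    Diffusion and Jump-Diffusion Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of Kramers-Moyal coefficients from uniformly sampled
    time series with exact finite-time corrections of arbitrary order. The
    naive estimator Dn ~ Mn/(n! dt) is biased at finite sampling intervals;
    the exact polynomial relation between conditional moments and
    Kramers-Moyal coefficients, expressed through partial ordinary and
    exponential Bell polynomials, is inverted symbolically (exact rational
    arithmetic) and numerically to remove that bias at any order. Includes an
    Euler-Maruyama simulator for Ornstein-Uhlenbeck and Poissonian
    jump-diffusion processes, non-parametric conditional-moment estimators
    (histogram and Nadaraya-Watson), recovery of drift, diffusion and jump
    parameters from corrected higher-order coefficients, and a classifier
    separating purely diffusive from jump-diffusion dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
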