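Package: handgp
Title: Non-Parametric Drug-Combination Synergy Scoring with Gaussian
    Processes and the Hand Null Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies synergy and antagonism in two-compound checkerboard
    dose-response experiments. Fits the full response surface with a Gaussian
    process using a logarithmic squared-exponential kernel suited to log-dose
    pharmacology, builds a non-interactive null reference surface from the
    fitted monotherapy curves by the Hand construction (the infinitesimal
    form of Loewe additivity), and scores interaction by the difference of
    the volumes under the two surfaces, with per-dose synergy calls and
    credible intervals. Hyperparameters are inferred by Hamiltonian Monte
    Carlo under Gamma priors, or by fast MAP optimisation. Hill-curve and
    MuSyC response-surface baselines with parametric-bootstrap confidence
    intervals are included for comparison, together with a Greco-type Loewe
    interaction simulator for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
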