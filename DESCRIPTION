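Package: perisk
Title: Probabilistic Ecological Risk Assessment of Heavy Metals in Marine
    Sediments and Seawater
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic ecological risk assessment of heavy
    metals (As, Cd, Cr, Cu, Hg, Pb, Zn) in coastal systems. Implements the
    Hakanson potential ecological risk index for sediments refined by Monte
    Carlo propagation of fitted concentration distributions, and an aquatic
    track based on species sensitivity distributions: HC5 and predicted
    no-effect concentrations, hazard quotients, joint probability curves and
    the overall risk probability. Includes maximum-likelihood fitting of
    log-normal, log-logistic, Weibull and Burr III distributions with
    Kolmogorov-Smirnov, Anderson-Darling and AIC model selection, chronic
    toxicity screening rules, and a synthetic survey generator that emulates
    a two-season field campaign.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    ggplot2,
    withr
Config/testthat/edition: 3
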