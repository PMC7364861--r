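Package: hpaxis
Title: Gland-Mass Dynamics of the HPA Stress-Hormone Axis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and analysis toolkit for a hypothalamic-pituitary-
    adrenal (HPA) axis model in which the hormones CRH and ACTH act as
    growth factors for the functional mass of their downstream glands.
    Provides the gland-mass circuit, the classic constant-mass cascade and
    three alternative slow-process variants behind one interface; a
    deterministic adaptive ODE engine with event-aware breakpoints; CRH
    stimulation-test simulation with response-ratio timelines and
    withdrawal-phase classification; and parameter sweeps over
    glucocorticoid-receptor feedback strength.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
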