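Package: mnbda
Title: Multi-Network Network-Based Diffusion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating social transmission of information across
    multiple weighted social networks. Builds simple-ratio-index association
    networks from co-observation streams, splits them into attribute-defined
    layers (e.g. conspecific versus heterospecific edges), and fits the
    continuous time-of-acquisition variant of network-based diffusion
    analysis (NBDA) with a per-layer transmission rate, individual-level
    covariates, tie masking of near-simultaneous discoveries, and constant
    or Weibull baseline hazards. Includes AICc multimodel inference with
    Akaike weights, model averaging and profile-likelihood confidence
    intervals, a decomposition of discovery events into social and asocial
    fractions, and an event-driven simulator for generating diffusions and
    observation streams from the same hazard model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
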