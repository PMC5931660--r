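Package: leafecon
Title: Leaf Economics and Photosynthetic Light-Response Analysis for
    Native-Invasive Species Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing leaf carbon-capture strategies between
    groups of co-occurring woody species (e.g. native evergreen, native
    deciduous, and invasive deciduous species). Fits four-parameter
    non-rectangular hyperbola photosynthetic light-response curves per
    leaf by maximum likelihood and hierarchically by MCMC (JAGS) with
    species- and individual-level random effects; derives light
    compensation points, leaf construction costs from carbon, nitrogen
    and ash concentrations, and nitrogen-, energy- and water-use
    efficiencies; tests univariate group differences by nativity and
    leaf habit with hierarchical Bayesian models; and performs
    standardized major axis (SMA) trait-scaling inference with
    common-slope, elevation and shift-along-axis tests. Includes a
    synthetic-data generator that emulates a typical study design with
    known ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
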