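Package: chromatch
Title: Quantifying Dynamic Background Matching Through Predator Vision
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying animal colour change and camouflage
    against experimental backgrounds through the eyes of an avian predator.
    Calibrates multiband photographs with grey reflectance standards, maps
    region-of-interest reflectances to cone quantum catches under a
    violet-sensitive trichromat plus double-cone receptor set, computes
    receptor-noise-limited chromatic and achromatic just-noticeable
    differences, decomposes patterning into a bandpass energy spectrum over a
    geometric series of spatial scales (dominant scale and pattern
    distribution difference), and fits linear mixed-effects trend models of
    background matching over time with pairwise slope contrasts under
    Benjamini-Hochberg correction. Includes a synthetic-experiment generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    emmeans,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
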