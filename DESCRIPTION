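Package: lissastab
Title: Perceptual Stability Analysis for Bistable Lissajous Figures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of bistable perception of rotating
    Lissajous figures under a 2x2 design varying shifting frequency and
    stimulus size. Provides the stimulus and self-occlusion geometry
    (occlusion phases, event schedules, overlap durations), synthetic
    observers that emit button-press event logs, preprocessing of event
    logs into occlusion-locked trial series, the conventional analysis
    (transition probabilities and a within-subject 2x2 ANOVA with partial
    eta squared), a trial-by-trial generative Bayesian model of perceptual
    stability in which the precision of a stability prior decays by a
    precision-weighted prediction error, maximum-a-posteriori model
    inversion with a Laplace approximation to the log-model evidence, and
    random-effects Bayesian model selection with exceedance probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
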