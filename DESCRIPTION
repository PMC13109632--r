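Package: pursuitlst
Title: Latent State-Trait Modeling of Smooth Pursuit Eye Movement Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end analysis of smooth pursuit eye movement (SPEM)
    performance across repeated measurement occasions. Extracts velocity
    gain, root mean square error (RMSE) and saccade frequency from gaze
    recordings of sinusoidal and triangular pursuit tasks; fits latent
    state (LS), latent state-trait (LST), and second-order latent growth
    curve (LGC) structural equation models by full-information maximum
    likelihood with robust (sandwich / scaled test statistic) corrections;
    tests longitudinal measurement invariance; decomposes observed variance
    into reliability, consistency (trait) and occasion specificity (state)
    components; and computes classical reliability coefficients (Cronbach's
    alpha with half-cycle equalization, split-half Spearman, ICC(A,1),
    repeated-measures ANOVA with Greenhouse-Geisser correction). Includes a
    synthetic-data generator with known ground truth for gaze traces and
    latent-level datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
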