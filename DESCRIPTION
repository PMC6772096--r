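Package: neonicbirds
Title: Spatio-Temporal Neonicotinoid Exposure and Farmland Bird Population Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking regional neonicotinoid seed-treatment
    usage to farmland bird population growth. Regional usage surveys are
    disaggregated to 5x5 km grid squares in proportion to cropped area,
    weighted by avian toxicity equivalency factors (acute LD50 or chronic
    LOAEL basis), and entered as a cumulative exposure covariate in a
    per-species log-linear mixed model with year effects and crossed random
    intercepts for grid square, survey site and region. Species are assigned
    to dietary exposure groups from the proportion of high-residue food items
    (treated seed and seedlings) in life-stage diets, and species-level
    exposure coefficients are compared across groups and regressed on diet
    proportions. A synthetic-data generator reproduces the statistical
    structure of the survey inputs so every stage is testable without
    licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
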