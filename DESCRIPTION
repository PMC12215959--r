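Package: reefbeauty
Title: Quantifying the Aesthetic Value of Coral Reef Benthic Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully synthetic re-implementation of a pipeline for
    quantifying the aesthetic value of coral-reef benthic communities from
    standardized quadrat photographs. Generates synthetic quadrat images with
    ground-truth benthic masks for healthy, restored and degraded reef
    habitats; simulates survey respondents making pairwise aesthetic choices
    under a logistic (Elo-consistent) rule; converts choices into per-photo
    Elo aesthetic ratings with randomized-order bootstrapping; extracts the
    colour and shape features of each photograph (64-bin RGB colour
    thumbprint, colour-group shares, Gini-Simpson colour diversity, colour
    richness, point-intercept benthic cover, coral morphology richness);
    trains a small convolutional image-to-rating regressor with the 70/15/15
    split and flip/rotation augmentation protocol; and analyses the results
    with correlation-threshold feature screening, backward stepwise
    regression, LMG variance-importance decomposition, mixed-effects habitat
    comparisons with Tukey HSD letters, and a binomial GLMM test of
    respondent socio-cultural effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
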