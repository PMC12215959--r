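---
title: "Methods: quantifying reef aesthetic value on a synthetic benthos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying reef aesthetic value on a synthetic benthos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
procedures, the parameters that matter, what the synthetic world emulates,
the numerical choices, and the limits of what a green test establishes.

## 1. The pipeline

Benthic quadrat photographs (50 × 50 cm, standardized to a square pixel
grid) are scored for aesthetic value in three coupled stages:

1. **Human preference → Elo rating.** Survey participants repeatedly choose
   the more beautiful of two randomly paired photographs. Each choice
   updates the two photos' ratings by the Elo rule; because a single
   sequential pass depends on the order of records, the pass is repeated in
   `n_bootstrap` shuffled orders and the per-photo mean is reported, with
   the across-run SD as order uncertainty.
2. **Image → rating regressor.** The rated subset trains an image regressor
   (70/15/15 train/validation/test, rotation and flip augmentation,
   best epoch chosen by validation loss). Accuracy is the squared Pearson
   correlation between predictions and held-out test ratings. The trained
   model predicts ratings for the full photo set.
3. **Explanation and comparison.** Nine photograph features (colour
   diversity, five colour-group shares, colour richness, growth-form
   richness, live coral cover) are screened for collinearity (|r| > 0.7,
   keeping the feature closer to the rating), reduced by backward stepwise
   OLS (drop the largest p > 0.05), and decomposed into LMG importance
   shares. Each retained response is compared across habitats with
   `value ~ habitat + (1 | site)` mixed models, likelihood-ratio tests
   against the no-habitat null, and Tukey HSD letters. A binomial GLMM with
   photo random intercepts tests whether respondent socio-cultural
   attributes influence choices.

## 2. The synthetic world

The package's generator replaces the field photographs so that every stage
can be verified against known truth.

**Covers.** Hard-coral and rubble cover are drawn per quadrat from beta
distributions on [0, 100] whose mean and SD equal the field survey values
(healthy 70.46 ± 23.02% coral, 5.89 ± 14.70% rubble; degraded 11.71 ± 21.27
and 74.91 ± 29.64; restored 61.32 ± 22.01 and 10.36 ± 15.92). We use
moment-matched betas rather than a truncated normal because truncating
N(70.46, 23.02) at [0, 100] drags the realized mean to ~66% — the generated
data would no longer have the stated means. When a joint draw exceeds 100%,
the excess is trimmed from the *minor* class so the habitat's dominant class
keeps its stated distribution (proportional rescaling biases degraded rubble
by ~4 percentage points).

**Rendering.** Colonies are parametric stamps per growth form (dendritic
walks for branching, lobed blobs for massive/submassive, discs for tabulate
and mushroom, disc unions for encrusting, annulus sectors for foliose,
finger rows for digitate); rubble is grey blobs, restored quadrats carry ~3%
dark frame bars, the rest is sand. The label mask is exact: ground-truth
cover *is* the pixel fraction, and the cover-estimation tests compare the
50-point estimator against it. Near-black shadow pixels are painted adjacent
to colonies at a fraction `shadow_scale × coral_cover × U(0.3, 1)` of the
image — the black colour group is the structural-complexity proxy.

**Community structure.** Each quadrat draws a random subset of its habitat's
colour archetypes with Dirichlet abundance weights (concentration
U(0.3, 3)) and a random subset of its growth-form pool; colony radii are
log-uniform, so single large colonies can dominate. These three draws make
colour richness, colour *evenness* and morphology richness vary
independently of coral cover — without them every feature is a proxy for
cover, all pairwise feature correlations exceed 0.7, and the screening step
degenerates (the field data show weak feature correlations). Sites
additionally draw their own archetype and growth-form subsets plus a
coral-cover shift (SD `site_cover_sd` = 8 points), giving the site random
intercept genuine variance.

**Latent aesthetic score.** The recoverable signal is
`700 × colour_diversity + 4.5 × min(coral_cover, 50) + 10 × n_morphologies
+ noise`, with `noise ~ N(0, 50)` rating points, expressed on the Elo scale
(a 400-point gap means a 10/11 win probability, which keeps choice
simulation and Elo recovery self-consistent). Two choices deserve comment:

* *Saturation at 50% cover.* Aesthetic returns to additional coral diminish
  once a quadrat reads as coral-dominated. This is what makes healthy (70%
  cover) and restored (61%) reefs perceptually equivalent while degraded
  (12%) falls far below — the central qualitative structure of the system
  this package models. With a linear cover term, healthy and restored reefs
  separate significantly at survey scale, contradicting that structure.
* *Diversity on the 64-bin thumbprint.* The latent colour-diversity feature
  is the same Gini–Simpson quantity the analysis later measures, so the
  "true" driver is well-defined and measurable. The weights put colour
  diversity and (saturated) cover on comparable variance shares, which is
  how the two top drivers rank in this system.

The latent linear model is plumbing for recovery testing, not a claim about
human perception; no published latent structure of preference exists to
copy.

**Respondents.** Attribute frequencies (country, education, diving
experience, coral knowledge) follow the published survey breakdown; gender
and age splits are not published and use broad defaults. Colour-vision
deficiency is flagged at the observed 96/3348 rate and flagged respondents
are excluded before rating. Attribute effects on choices default to zero —
the survey found none — but `simulate_choices(attr_effects =)` can shift the
first-shown photo's effective score per attribute level, giving the
respondent GLMM a detectable signal for power tests.

## 3. Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `elo_config(start_value, k_factor)` | 0, 100 | rating points | The source analysis does not publish them; these are the cited rating package's defaults. Absolute scale cancels in every rank-based or linear downstream step. |
| `elo_config(n_bootstrap)` | 1000 | runs | Survey protocol value; runs are vectorised so this costs seconds. |
| `simulate_choices(pairs_each)` | 30 | pairs | Survey protocol. |
| `study_config(n_respondents)` | 400 | people | Desk-scale stand-in for 3,348; enough that Elo measurement noise does not dominate the predictor's training targets. |
| `predictor_config(input_side)` | 64 | px | Desk scale; the network geometry requires (side−4)/4 − 3 divisible by 3. |
| `predictor_config(epochs, n_filters1, n_filters2, n_hidden)` | 60, 8, 24, 96 | — | Smallest configuration whose predictions transmit colour evenness, not only colour counts; smaller heads distort the importance decomposition downstream. |
| `point_count_cover(n_points)` | 50 | points | Survey protocol (each point worth 2%). |
| `count_colours(threshold)` | 0.01 | proportion | Strictly-greater-than 1% rule. |
| `correlation_filter(threshold)` | 0.7 | \|r\| | Source analysis value. |
| `backward_stepwise(alpha)` | 0.05 | p | Source analysis value. |
| `study_config(qc_fail_prob)` | 17/900 | probability | Observed QC discard rate; drawn as an exact count so the default study reproduces 883 of 900. |

## 4. Numerical choices

* **Standardization** centre-crops to square then resamples by
  nearest-neighbour index mapping — deterministic, and an already-sized
  input passes through bit-identically.
* **Thumbprint bins** are half-open `[0,64), [64,128), [128,192), [192,256)`
  per channel, red-major order. The published bin→group table is not in the
  main text; the default mapping (black = all-lowest, grey = equal divisions
  above lowest, dominant-channel rules for blue/green/yellow, remainder
  "other") ships as an editable CSV (`inst/extdata/colour_bin_groups.csv`)
  so the published table can be dropped in.
* **Simpson index** defaults to the 64 bins (the stated unit of the colour
  analysis); a group-level switch exists in `assemble_features()`.
* **Elo bootstrap** shuffling uses one master seed spawning per-run
  substreams; total rating is conserved exactly per run, so the grand mean
  equals the start value to machine precision (a conservation test).
* **LRTs** compare maximum-likelihood fits; Gaussian parameter estimates are
  refit by REML. Singular random-effect fits are flagged, not hidden.
* **Gamma-log responses**: zeros are nudged to half the smallest positive
  observation (a machine-epsilon floor sits ~36 log-units below the data and
  breaks PIRLS convergence); the nudge count is recorded.
* **Tukey HSD** is computed from the fitted model's fixed-effect covariance
  with the studentized-range distribution (no multiple-comparison package is
  assumed): reference df = sites − habitats for the Gaussian LMM, normal
  reference for GLMMs. Letters are maximal cliques of the
  non-significant-difference graph.
* **Stepwise ties** in the maximal p-value drop the alphabetically first
  name; the correlation filter breaks target-correlation ties the same way —
  determinism over elegance.
* **Degenerate inputs**: a zero-variance response returns χ² = 0, p = 1 with
  a single shared letter rather than an `lmer` failure; constant features
  are dropped from screening with a warning; constant predictions raise an
  error in `evaluate_r2` (the correlation is undefined).
* **Seeds** everywhere derive from a master seed via a 31-bit string hash
  (`substream_seed`), so stages are independently reproducible and all
  derived seeds stay below 2³¹.

## 5. Design choices where the design was open

* **Importance method.** The source prints per-feature variance shares
  without naming the method; LMG (sequential R² averaged over all
  orderings, computed exactly via the all-subsets identity) is the default,
  with squared-standardised-coefficient shares as `method = "betasq"`.
  Results carry the method used.
* **Predictor backend.** No deep-learning framework is assumed: the
  `small_cnn` backend is a from-scratch convolutional regressor (im2col +
  BLAS) preserving the original protocol; `linear_on_features` is a
  transparent fallback. ImageNet transfer learning is out of scope by
  design.
* **Stepwise stage** is plain OLS (the source describes the model both as
  multiple regression and as a mixed model); the habitat comparisons are
  where the site random effect lives.
* **Point placement** is without replacement at pixel centres, seed
  recorded; with vs without replacement is unstated in the source and
  immaterial at 50 points on ≥4,096 pixels.
* **LRT df** is the true parameter-count difference (2 for a three-level
  habitat effect); the source prints df = 3 for its GLMMs, which we do not
  emulate.

## 6. What a green test does and does not establish

The synthetic world shares the field system's *statistical structure* —
cover distributions, habitat contrasts, weakly correlated features, a
choice rule consistent with Elo — but not its *appearance*: no water column,
lighting, fish, texture, or camera artefacts. Green tests establish that
every algorithm does what it claims on data of known truth (cover estimation
is unbiased, Elo recovers latent order, the predictor learns real signal and
not shuffled labels, type-I error is nominal, the full chain reproduces the
qualitative habitat pattern). They do not establish that the original
headline numbers (prediction R² = 0.95, the printed importance percentages,
the rating range) would be reproduced on real photographs — those are
properties of the field data and of an ImageNet-pretrained backbone, both
outside this package.

## 7. Known limitations

* The renderer's schematic shapes make morphology recognition from pixels
  trivial compared to real photographs; morphology features therefore come
  from the mask, never from image inference.
* Elo ratings are reported as across-run means; respondent-specific
  reliability, Bradley–Terry likelihoods and tie handling are out of scope.
* The respondent GLMM's left/right encoding detects attribute-linked
  position bias (how the simulator injects effects); attribute × content
  interactions are not modelled.
* At 64 px the colour thumbprint is coarser than at the survey's 700 px;
  all defaults keep the two sides of each comparison at the same scale.
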