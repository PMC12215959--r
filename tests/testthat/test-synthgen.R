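test_that("preset validation names the offending field", {
  expect_error(habitat_preset("healthy", coral_cover_mean = 120,
                              coral_cover_sd = 10, rubble_cover_mean = 5,
                              rubble_cover_sd = 5),
               "coral_cover_mean")
  expect_error(habitat_preset("healthy", coral_cover_mean = 50,
                              coral_cover_sd = -1, rubble_cover_mean = 5,
                              rubble_cover_sd = 5),
               "coral_cover_sd")
  expect_error(habitat_preset("healthy", coral_cover_mean = 50,
                              coral_cover_sd = 10, rubble_cover_mean = 5,
                              rubble_cover_sd = 5,
                              morphology_pool = c("branching", "nonsense")),
               "morphology_pool")
  expect_error(habitat_preset("swamp", coral_cover_mean = 50,
                              coral_cover_sd = 10, rubble_cover_mean = 5,
                              rubble_cover_sd = 5),
               "name")
})

test_that("zero-cover preset yields a mask with no coral pixels", {
  p <- habitat_preset("degraded", coral_cover_mean = 0, coral_cover_sd = 0,
                      rubble_cover_mean = 50, rubble_cover_sd = 10,
                      morphology_pool = "encrusting",
                      palette = default_coral_palette(drab = TRUE))
  g <- generate_quadrat(p, seed = 5, side = 32)
  expect_equal(unname(g$truth$true_cover["hard_coral"]), 0)
  expect_false(any(g$mask$labels >= 10L))
  expect_equal(morphology_richness(g$mask), 0)
})

test_that("ground-truth cover equals exact pixel counting and sums to 100", {
  presets <- default_habitat_presets()
  for (seed in c(3, 17, 91)) {
    for (hab in names(presets)) {
      g <- generate_quadrat(presets[[hab]], seed = seed, side = 48)
      expect_equal(g$truth$true_cover, exact_cover(g$mask))
      expect_equal(sum(g$truth$true_cover), 100, tolerance = 1e-12)
      expect_true(all(g$truth$true_cover >= 0))
      # image and mask share dimensions
      expect_identical(dim(g$image$pixels)[1:2], dim(g$mask$labels))
      # every coral pixel carries one of the 8 morphology labels
      labs <- g$mask$labels[g$mask$labels >= 10L]
      expect_true(all(labs %in% (10L + seq_len(8L))))
      expect_true(is.finite(g$truth$latent_aesthetic))
    }
  }
})

test_that("generation is bit-identical under the same seed", {
  p <- default_habitat_presets()$restored
  g1 <- generate_quadrat(p, seed = 77, side = 40)
  g2 <- generate_quadrat(p, seed = 77, side = 40)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(g1$mask$labels, g2$mask$labels)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_quadrat(p, seed = 78, side = 40)
  expect_false(identical(g1$image$pixels, g3$image$pixels))
})

test_that("shadow pixels are near-black and frames render in restored quadrats", {
  p <- default_habitat_presets()$restored
  g <- generate_quadrat(p, seed = 21, side = 64)
  expect_gt(unname(g$truth$true_cover["frame"]), 0)
  # black group share in the rendered image reflects shadowing
  expect_gt(unname(g$truth$true_colour_shares["black"]), 0)
})

test_that("latent_score follows its closed-form cases", {
  g <- generate_quadrat(default_habitat_presets()$healthy, seed = 8, side = 32)
  w0 <- c(colour_diversity = 0, coral_cover = 0, n_morphologies = 0,
          rubble_cover = 0)
  expect_equal(latent_score(g$truth, w0, noise_sd = 0), 0)
  expect_error(latent_score(g$truth, c(bad_name = 1), noise_sd = 0), "named")

  # unit weight on coral cover only: scores ordered by true cover (monotone
  # non-decreasing; the aesthetic return on cover saturates at 50%)
  w_coral <- c(colour_diversity = 0, coral_cover = 1, n_morphologies = 0,
               rubble_cover = 0)
  gs <- lapply(1:12, function(s)
    generate_quadrat(default_habitat_presets()$degraded, seed = 100 + s,
                     side = 32))
  covers <- vapply(gs, function(g) unname(g$truth$true_cover["hard_coral"]),
                   numeric(1))
  scores <- vapply(gs, function(g) latent_score(g$truth, w_coral, noise_sd = 0),
                   numeric(1))
  expect_true(all(diff(scores[order(covers)]) >= -1e-12))
  expect_equal(scores, pmin(covers, 50))
})

test_that("default latent weights put positive rank signal on coral cover", {
  presets <- default_habitat_presets()
  habs <- rep(names(presets), length.out = 200)
  covers <- numeric(200); scores <- numeric(200)
  for (i in seq_len(200)) {
    g <- generate_quadrat(presets[[habs[i]]], seed = 5000 + i, side = 32)
    covers[i] <- g$truth$true_cover["hard_coral"]
    scores[i] <- g$truth$latent_aesthetic
  }
  expect_gt(cor(scores, covers, method = "spearman"), 0)
})

test_that("choice simulation is calibrated to the logistic rule", {
  # closed forms: gap 0 -> 0.5; gap 400 -> 10/11
  expect_equal(elo_win_prob(0, 0), 0.5)
  expect_equal(elo_win_prob(400, 0), 10 / 11)
  for (gap in c(0, 200, 400)) {
    scores <- c(a = gap, b = 0)
    rec <- simulate_choices(scores, n_respondents = 10000, pairs_each = 1,
                            seed = 400 + gap)
    # wins of the stronger image regardless of presentation side
    wins_a <- mean(rec$winner == "a")
    p_expected <- elo_win_prob(gap, 0)
    # 10^4 trials: 4 binomial SDs is at most 0.02
    expect_lt(abs(wins_a - p_expected), 4 * sqrt(0.25 / 10000) + 1e-12)
  }
})

test_that("simulate_choices respects the survey protocol", {
  scores <- toy_scores(20)
  rec <- simulate_choices(scores, n_respondents = 100, pairs_each = 30,
                          seed = 2)
  expect_equal(nrow(rec), 3000)
  expect_true(all(rec$photo_a != rec$photo_b))
  expect_true(all(rec$winner == rec$photo_a | rec$winner == rec$photo_b))
  # pairs are distinct within a respondent
  key <- paste(pmin(rec$photo_a, rec$photo_b), pmax(rec$photo_a, rec$photo_b))
  dup <- tapply(key, rec$respondent_id, anyDuplicated)
  expect_true(all(dup == 0))
  # determinism and error cases
  rec2 <- simulate_choices(scores, n_respondents = 100, pairs_each = 30,
                           seed = 2)
  expect_identical(rec, rec2)
  expect_error(simulate_choices(c(a = 1), 10), "2 images")
  expect_error(simulate_choices(toy_scores(3), 10, pairs_each = 30), "pairs_each")
})

test_that("colour-deficiency exclusion removes exactly the flagged respondents", {
  resp <- simulate_respondents(100, seed = 3, p_colour_deficient = 0)
  resp$colour_deficiency[1:5] <- TRUE
  rec <- simulate_choices(toy_scores(10), n_respondents = 100, pairs_each = 3,
                          respondents = resp, seed = 4)
  kept <- exclude_colour_deficient(rec)
  expect_equal(length(unique(kept$respondent_id)), 95)
  expect_false(any(kept$colour_deficiency))
  # order preserved
  expect_identical(kept$respondent_id,
                   rec$respondent_id[!rec$colour_deficiency])
  # no flags: identity
  rec0 <- rec[!rec$colour_deficiency, ]
  rownames(rec0) <- NULL
  expect_identical(exclude_colour_deficient(rec0), rec0)
  # all flagged: empty output with a warning
  rec_all <- rec
  rec_all$colour_deficiency <- TRUE
  expect_warning(out <- exclude_colour_deficient(rec_all), "no records")
  expect_equal(nrow(out), 0)
})
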