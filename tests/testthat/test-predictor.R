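test_that("split_dataset sizes follow largest-remainder rounding", {
  sp300 <- split_dataset(sprintf("i%03d", 1:300), seed = 1)
  expect_equal(lengths(sp300), c(train = 210L, val = 45L, test = 45L))
  sp20 <- split_dataset(sprintf("i%02d", 1:20), seed = 1)
  expect_equal(lengths(sp20), c(train = 14L, val = 3L, test = 3L))
  expect_error(split_dataset(letters, fractions = c(0.5, 0.3, 0.3)), "sum to 1")
  expect_error(split_dataset(c("a", "a", "b")), "unique")
})

test_that("split_dataset is a deterministic partition", {
  for (n in c(7, 33, 100)) {
    ids <- sprintf("x%03d", seq_len(n))
    sp <- split_dataset(ids, seed = n)
    expect_setequal(c(sp$train, sp$val, sp$test), ids)
    expect_equal(anyDuplicated(c(sp$train, sp$val, sp$test)), 0)
    expect_identical(sp, split_dataset(ids, seed = n))
  }
})

test_that("flips are involutions and rotation by 0 is the identity", {
  g <- generate_quadrat(default_habitat_presets()$healthy, seed = 2, side = 32)
  px <- g$image$pixels
  expect_identical(flip_image(flip_image(px, "v"), "v"), px)
  expect_identical(flip_image(flip_image(px, "h"), "h"), px)
  expect_identical(rotate_image(px, 0), px)
  expect_identical(rotate_image(px, 360), px)
  expect_error(augment_image(px, augmentations = "zoom"), "unknown")
})

test_that("flips leave the colour thumbprint unchanged", {
  g <- generate_quadrat(default_habitat_presets()$restored, seed = 4, side = 32)
  px <- g$image$pixels
  tp <- colour_thumbprint(px)$proportions
  expect_equal(colour_thumbprint(flip_image(px, "h"))$proportions, tp)
  expect_equal(colour_thumbprint(flip_image(px, "v"))$proportions, tp)
  aug <- augment_image(px, augmentations = c("hflip", "vflip"), seed = 5)
  expect_equal(colour_thumbprint(aug)$proportions, tp)
  expect_equal(dim(augment_image(px, seed = 6)), dim(px))
})

test_that("evaluate_r2 handles the degenerate and adversarial cases", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(evaluate_r2(y, y), 1)
  expect_error(evaluate_r2(rep(1, 5), y), "constant")
  expect_error(evaluate_r2(y[1:2], y[1:2]), "at least 3")
  expect_warning(r2 <- evaluate_r2(-y, y), "anti-correlated")
  expect_equal(r2, 1)
})

test_that("linear backend attains near-perfect fit on a realizable target", {
  n <- 60
  feats <- withr::with_seed(1, data.frame(
    image_id = sprintf("i%02d", 1:n),
    f1 = stats::rnorm(n), f2 = stats::rnorm(n), f3 = stats::rnorm(n)))
  y <- stats::setNames(2 * feats$f1 - feats$f2 + 0.5 * feats$f3 + 10,
                       feats$image_id)
  sp <- split_dataset(feats$image_id, seed = 2)
  m <- train_predictor(NULL, y, sp$train, sp$val,
                       predictor_config(backend = "linear_on_features"),
                       features = feats)
  pred <- predict_ratings(m, ids = sp$val)
  expect_gt(evaluate_r2(pred, y[sp$val]), 0.99)
  expect_error(train_predictor(NULL, y, character(0), sp$val,
                               predictor_config(backend = "linear_on_features"),
                               features = feats), "empty training set")
})

test_that("training never reads images outside the train and val sets", {
  presets <- default_habitat_presets()
  imgs <- list()
  for (i in 1:20) {
    g <- generate_quadrat(presets$healthy, seed = 600 + i, side = 64,
                          image_id = paste0("im", i))
    imgs[[g$image$image_id]] <- g$image$pixels
  }
  y <- stats::setNames(stats::rnorm(20, 1000, 100), names(imgs))
  sp <- split_dataset(names(imgs), seed = 3)
  accessed <- character(0)
  loader <- function(id) {
    accessed <<- c(accessed, id)
    imgs[[id]]
  }
  cfg <- predictor_config(epochs = 1, seed = 1, augmentations = character(0))
  m <- train_predictor(loader, y, sp$train, sp$val, cfg)
  expect_setequal(unique(accessed), c(sp$train, sp$val))
  expect_false(any(sp$test %in% accessed))
})

test_that("small CNN training is deterministic and prediction is finite", {
  presets <- default_habitat_presets()
  imgs <- list(); y <- numeric(0)
  for (i in 1:24) {
    hab <- c("healthy", "degraded")[1 + i %% 2]
    g <- generate_quadrat(presets[[hab]], seed = 700 + i, side = 64,
                          image_id = paste0("im", i))
    imgs[[g$image$image_id]] <- g$image
    y[g$image$image_id] <- g$truth$latent_aesthetic
  }
  sp <- split_dataset(names(imgs), seed = 5)
  cfg <- predictor_config(epochs = 2, batch_size = 8, seed = 9)
  m1 <- train_predictor(imgs, y, sp$train, sp$val, cfg)
  m2 <- train_predictor(imgs, y, sp$train, sp$val, cfg)
  expect_identical(m1$par, m2$par)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 2)
  expect_gte(m1$best_epoch, 1)
  p1 <- predict_ratings(m1, imgs)
  expect_length(p1, 24)
  expect_true(all(is.finite(p1)))
  expect_identical(p1, predict_ratings(m2, imgs))
})
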