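test_that("standardize_image follows the crop-and-resample rule", {
  big <- array(rep(as.integer(seq_len(1400) %% 256), 1400 * 3),
               dim = c(1400, 1400, 3))
  out <- standardize_image(big, 700)
  expect_equal(dim(out), c(700, 700, 3))

  same <- array(7L, dim = c(700, 700, 3))
  expect_identical(standardize_image(same, 700), same)

  rect <- array(0L, dim = c(800, 600, 3))
  rect[, , 1] <- 9L
  out2 <- standardize_image(rect, 700)
  expect_equal(dim(out2), c(700, 700, 3))
  # centre crop: a 600-wide input is cropped to the middle 600 rows then
  # upsampled; content here is uniform so values must be preserved
  expect_true(all(out2[, , 1] == 9L))

  expect_error(standardize_image(array(0L, dim = c(10, 10, 2))), "3 colour")
})

test_that("downsampling by an integer factor picks exact source pixels", {
  x <- array(0L, dim = c(8, 8, 3))
  x[, , 1] <- as.integer(matrix(seq_len(64) - 1, 8, 8))
  out <- standardize_image(x, 4)
  # nearest-neighbour mapping: output pixel i comes from source floor((i - 0.5) * 2) + 1 = 2i
  expect_identical(out[, , 1], x[c(2, 4, 6, 8), c(2, 4, 6, 8), 1])
})

test_that("colour thumbprint closed-form cases", {
  tp_black <- colour_thumbprint(solid_image(c(0, 0, 0)))
  expect_equal(tp_black$proportions[1], 1)
  expect_equal(sum(tp_black$proportions), 1)

  tp2 <- colour_thumbprint(half_half_image(c(0, 0, 255), c(255, 255, 0)))
  expect_equal(sort(tp2$proportions[tp2$proportions > 0]), c(0.5, 0.5))
  expect_equal(length(tp2$proportions), 64)
  expect_equal(sum(tp2$proportions), 1)

  g <- generate_quadrat(default_habitat_presets()$healthy, seed = 1, side = 32)
  tp3 <- colour_thumbprint(g$image)
  expect_equal(length(tp3$proportions), 64)
  expect_equal(sum(tp3$proportions), 1, tolerance = 1e-12)
})

test_that("thumbprint is invariant to pixel permutation", {
  g <- generate_quadrat(default_habitat_presets()$restored, seed = 9, side = 32)
  px <- g$image$pixels
  n <- prod(dim(px)[1:2])
  perm <- withr::with_seed(1, sample.int(n))
  shuffled <- px
  for (ch in 1:3) {
    plane <- px[, , ch]
    shuffled[, , ch] <- matrix(plane[perm], dim(px)[1], dim(px)[2])
  }
  expect_equal(colour_thumbprint(px)$proportions,
               colour_thumbprint(shuffled)$proportions)
})

test_that("group shares match brute-force per-pixel counting", {
  # hand-counted construction: half black, quarter blue, quarter yellow
  side <- 8
  img <- solid_image(c(0, 0, 0), side)
  img[, 5:6, ] <- 0L; img[, 5:6, 3] <- 200L      # blue-dominant
  img[, 7:8, 1] <- 210L; img[, 7:8, 2] <- 210L   # r = g >> b
  gs <- group_shares(colour_thumbprint(img))
  expect_equal(unname(gs["black"]), 50)
  expect_equal(unname(gs["blue"]), 25)
  expect_equal(unname(gs["yellow"]), 25)
  expect_equal(sum(gs), 100, tolerance = 1e-9)

  expect_equal(unname(group_shares(colour_thumbprint(
    solid_image(c(10, 10, 10))))["black"]), 100)
})

test_that("group shares error on incomplete or duplicated mappings", {
  m <- default_bin_groups()
  tp <- colour_thumbprint(solid_image(c(0, 0, 0)))
  expect_error(group_shares(tp, m[-3, ]), "missing bins: 3")
  dup <- rbind(m, m[5, ])
  expect_error(group_shares(tp, dup), "double-assigned bins: 5")
  bad <- m; bad$group[2] <- "magenta"
  expect_error(group_shares(tp, bad), "magenta")
})

test_that("bin-group mapping round-trips through CSV", {
  path <- tempfile(fileext = ".csv")
  write_bin_groups(default_bin_groups(), path)
  expect_equal(read_bin_groups(path), default_bin_groups())
})

test_that("Simpson diversity closed forms and validation", {
  one <- c(1, rep(0, 63))
  expect_equal(simpson_diversity(one), 0)
  two <- c(0.5, 0.5, rep(0, 62))
  expect_equal(simpson_diversity(two), 0.5)
  expect_equal(simpson_diversity(rep(1 / 64, 64)), 1 - 1 / 64)
  expect_error(simpson_diversity(c(0.5, 0.4)), "sum to 1")
  expect_error(simpson_diversity(c(1.2, -0.2)), "non-negative")
})

test_that("Simpson diversity agrees with the community-ecology reference", {
  skip_if_not_installed("vegan")
  for (seed in 1:5) {
    p <- withr::with_seed(seed, {
      x <- stats::runif(64)
      x / sum(x)
    })
    expect_equal(simpson_diversity(p),
                 unname(vegan::diversity(p, index = "simpson")),
                 tolerance = 1e-12)
  }
})

test_that("Simpson is maximal at uniformity and zero only for one bin", {
  u <- simpson_diversity(rep(1 / 64, 64))
  for (seed in 1:10) {
    p <- withr::with_seed(seed, {
      x <- stats::rgamma(64, 0.5)
      x / sum(x)
    })
    d <- simpson_diversity(p)
    expect_lte(d, u)
    expect_gt(d, 0)
  }
})

test_that("count_colours applies a strict 1% threshold", {
  expect_equal(count_colours(colour_thumbprint(solid_image(c(30, 90, 200)))), 1)
  expect_equal(count_colours(rep(1 / 64, 64)), 64) # 1/64 ~ 1.56% > 1%
  # constructed boundary: 100x100 image with exactly 100 px (1.00%) of one
  # colour; that bin must be excluded by the strict inequality
  img <- solid_image(c(0, 0, 0), side = 100)
  img[1:100] <- 255L # first 100 pixels of the red channel -> bin (3,0,0)
  tp <- colour_thumbprint(img)
  expect_equal(sum(tp$proportions == 0.01), 1)
  expect_equal(count_colours(tp), 1)
  expect_equal(count_colours(tp, threshold = 0.0099), 2)
})
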