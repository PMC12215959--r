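test_that("correlation filter keeps the feature closer to the target", {
  n <- 200
  d <- withr::with_seed(1, {
    a <- stats::rnorm(n)
    data.frame(a = a, b = a + stats::rnorm(n, 0, 0.01), c = stats::rnorm(n))
  })
  # target correlates 0.6-ish with a, less with b by construction
  target <- withr::with_seed(2, 0.8 * d$a + stats::rnorm(n, 0, 1))
  target <- target + 0.05 * (d$a - d$b) # nudge a strictly above b
  out <- correlation_filter(d, target, threshold = 0.7)
  expect_true("a" %in% out$retained)
  expect_false("b" %in% out$retained)
  expect_equal(out$removals$dropped, "b")
  expect_gt(abs(out$removals$r_pair), 0.7)
})

test_that("correlation filter is the identity when no pair exceeds the threshold", {
  d <- withr::with_seed(3, as.data.frame(matrix(stats::rnorm(400), 100, 4)))
  target <- withr::with_seed(4, stats::rnorm(100))
  out <- correlation_filter(d, target)
  expect_setequal(out$retained, names(d))
  expect_equal(nrow(out$removals), 0)
})

test_that("correlation filter matches a hand-traced 3-feature chain", {
  # fixed fixture drawn from a known correlation matrix:
  # cor(A,B) = 0.85, cor(B,C) = 0.80, cor(A,C) = 0.50
  n <- 800
  R <- matrix(c(1, 0.85, 0.5, 0.85, 1, 0.8, 0.5, 0.8, 1), 3, 3)
  Z <- withr::with_seed(5, matrix(stats::rnorm(n * 3), n, 3)) %*% chol(R)
  d <- data.frame(A = Z[, 1], B = Z[, 2], C = Z[, 3])
  target <- withr::with_seed(6, d$A + 0.5 * stats::rnorm(n))
  # hand trace of the stated rule: the most-correlated pair is (A, B);
  # |cor(B, target)| < |cor(A, target)| so B is dropped; remaining pair
  # (A, C) is below the threshold -> retain {A, C}
  expect_gt(abs(cor(d$A, d$B)), 0.7)
  expect_gt(abs(cor(d$B, d$C)), 0.7)
  expect_lt(abs(cor(d$A, d$C)), 0.7)
  expect_gt(abs(cor(d$A, d$B)), abs(cor(d$B, d$C)))
  expect_gt(abs(cor(target, d$A)), abs(cor(target, d$B)))
  out <- correlation_filter(d, target, threshold = 0.7)
  expect_setequal(out$retained, c("A", "C"))
  expect_equal(out$removals$dropped, "B")
  # terminated state: no retained pair above the threshold
  cm <- abs(cor(d[, out$retained, drop = FALSE])); diag(cm) <- 0
  expect_lte(max(cm), 0.7)
})

test_that("constant features are dropped with a warning", {
  d <- data.frame(a = stats::rnorm(50), k = rep(1, 50))
  expect_warning(out <- correlation_filter(d, stats::rnorm(50)), "constant")
  expect_equal(out$retained, "a")
})

test_that("backward stepwise keeps exactly the signal features", {
  n <- 500
  d <- withr::with_seed(6, as.data.frame(matrix(stats::rnorm(n * 6), n, 6,
         dimnames = list(NULL, c("s1", "s2", "s3", "n1", "n2", "n3")))))
  y <- withr::with_seed(7, 3 * d$s1 - 2 * d$s2 + 1.5 * d$s3 +
                          stats::rnorm(n, 0, 0.1))
  fit <- backward_stepwise(d, y)
  expect_setequal(fit$retained, c("s1", "s2", "s3"))
  expect_gt(fit$r_squared, 0.99)
  expect_true(all(fit$coefficients$p_value <= 0.05))
})

test_that("stepwise retains a single significant feature unchanged", {
  d <- withr::with_seed(8, data.frame(x = stats::rnorm(100)))
  y <- 2 * d$x + withr::with_seed(9, stats::rnorm(100, 0, 0.5))
  fit <- backward_stepwise(d, y)
  expect_equal(fit$retained, "x")
  expect_equal(fit$eliminated, character(0))
})

test_that("pure-noise features are spuriously retained near the nominal rate", {
  hits <- vapply(1:150, function(s) {
    d <- withr::with_seed(1000 + s,
      as.data.frame(matrix(stats::rnorm(100 * 4), 100, 4)))
    y <- withr::with_seed(2000 + s, stats::rnorm(100))
    fit <- suppressWarnings(backward_stepwise(d, y))
    length(fit$retained) > 0
  }, logical(1))
  # with 4 independent noise features the familywise spurious-retention
  # probability is near 1 - 0.95^4 ~ 0.185; allow broad Monte-Carlo slack
  expect_gt(mean(hits), 0.05)
  expect_lt(mean(hits), 0.40)
})

test_that("stepwise retained set ignores feature column order", {
  n <- 300
  d <- withr::with_seed(10, as.data.frame(matrix(stats::rnorm(n * 4), n, 4,
        dimnames = list(NULL, c("a", "b", "c", "d")))))
  y <- withr::with_seed(11, 2 * d$a + d$c + stats::rnorm(n))
  f1 <- backward_stepwise(d, y)
  f2 <- backward_stepwise(d[, c("d", "c", "b", "a")], y)
  expect_setequal(f1$retained, f2$retained)
})

test_that("LMG importance equals brute-force enumeration over orderings", {
  n <- 200
  d <- withr::with_seed(12, {
    x1 <- stats::rnorm(n)
    x2 <- 0.5 * x1 + stats::rnorm(n)
    x3 <- stats::rnorm(n)
    data.frame(x1 = x1, x2 = x2, x3 = x3)
  })
  y <- withr::with_seed(13, d$x1 + 0.5 * d$x2 - 0.8 * d$x3 + stats::rnorm(n))
  # independent oracle: average sequential R2 increments over all 3! orderings
  r2_of <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(stats::lm(y ~ ., data = d[, cols, drop = FALSE]))$r.squared
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  contrib <- c(x1 = 0, x2 = 0, x3 = 0)
  for (pm in perms) {
    for (pos in 1:3) {
      j <- pm[pos]
      before <- names(d)[pm[seq_len(pos - 1)]]
      contrib[j] <- contrib[j] + (r2_of(c(before, names(d)[j])) - r2_of(before)) / 6
    }
  }
  oracle <- 100 * contrib / sum(contrib)
  shares <- importance_shares(d, y)
  expect_equal(as.numeric(shares), as.numeric(oracle), tolerance = 1e-10)
  expect_equal(sum(shares), 100, tolerance = 1e-9)
  # permutation invariance of the inputs
  shares_perm <- importance_shares(d[, c("x3", "x1", "x2")], y)
  expect_equal(as.numeric(shares_perm[names(shares)]), as.numeric(shares),
               tolerance = 1e-10)
})

test_that("importance closed forms: single feature and orthogonal pair", {
  d1 <- data.frame(x = stats::rnorm(50))
  y1 <- 2 * d1$x + stats::rnorm(50)
  expect_equal(as.numeric(importance_shares(d1, y1)), 100)

  # exactly orthogonal pair: shares proportional to squared correlations
  n <- 128
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  stopifnot(sum(x1 * x2) == 0)
  y <- withr::with_seed(14, 2 * x1 + x2 + stats::rnorm(n, 0, 0.5))
  d <- data.frame(x1 = x1, x2 = x2)
  shares <- importance_shares(d, y)
  expected <- c(cor(x1, y)^2, cor(x2, y)^2)
  expected <- 100 * expected / sum(expected)
  expect_equal(as.numeric(shares), expected, tolerance = 1e-8)
  expect_error(importance_shares(as.data.frame(matrix(rnorm(11 * 20), 20, 11)),
                                 rnorm(20)), "more than 10")
})

test_that("habitat mixed model recovers a strong effect with Tukey letters", {
  d <- withr::with_seed(15, {
    site <- rep(sprintf("s%02d", 1:18), each = 20)
    habitat <- rep(c("healthy", "restored", "degraded"), each = 120)
    mu <- c(healthy = 1500, restored = 1450, degraded = 900)[habitat]
    site_eff <- rep(stats::rnorm(18, 0, 40), each = 20)
    data.frame(value = mu + site_eff + stats::rnorm(360, 0, 80),
               habitat = habitat, site_id = site)
  })
  ht <- fit_habitat_model(d, family = "gaussian")
  expect_lt(ht$p, 0.001)
  expect_equal(ht$df, 2)
  post <- tukey_posthoc(ht)
  expect_equal(nrow(post$contrasts), 3)
  lt <- post$letters
  expect_equal(unname(lt["healthy"]), unname(lt["restored"]))
  expect_false(lt["degraded"] %in% lt[c("healthy", "restored")])
})

test_that("constant responses give a null test with a single shared letter", {
  d <- data.frame(value = rep(5, 90),
                  habitat = rep(c("healthy", "restored", "degraded"), each = 30),
                  site_id = rep(sprintf("s%d", 1:9), each = 10))
  ht <- fit_habitat_model(d, family = "gaussian")
  expect_equal(ht$chi2, 0)
  expect_equal(ht$p, 1)
  post <- tukey_posthoc(ht)
  expect_true(all(post$letters == "a"))
})

test_that("gamma and poisson families validate their support", {
  d <- data.frame(value = c(-1, rep(2, 89)),
                  habitat = rep(c("healthy", "restored", "degraded"), each = 30),
                  site_id = rep(sprintf("s%d", 1:9), each = 10))
  expect_error(fit_habitat_model(d, family = "gamma_log"), "non-negative")
  d$value <- c(1.5, rep(2, 89))
  expect_error(fit_habitat_model(d, family = "poisson"), "integer")
})

test_that("Tukey-adjusted p-values dominate the raw normal p-values", {
  d <- withr::with_seed(16, {
    site <- rep(sprintf("s%02d", 1:12), each = 15)
    habitat <- rep(c("healthy", "restored", "degraded"), each = 60)
    data.frame(value = stats::rnorm(180, 100, 10) +
                 (habitat == "degraded") * -8,
               habitat = habitat, site_id = site)
  })
  ht <- fit_habitat_model(d, family = "gaussian")
  post <- tukey_posthoc(ht)
  raw <- 2 * stats::pnorm(-abs(post$contrasts$z))
  expect_true(all(post$contrasts$p_adj >= raw - 1e-12))
})

test_that("respondent effects GLMM validates inputs and runs on null data", {
  scores <- toy_scores(20, spread = 600)
  rec <- simulate_choices(scores, n_respondents = 60, pairs_each = 15, seed = 17)
  rec <- exclude_colour_deficient(rec)
  expect_error(respondent_effects(rec[, 1:4]), "none of the requested")
  rec_one <- rec
  rec_one$gender <- "female"
  expect_warning(
    out1 <- respondent_effects(rec_one, attributes = c("gender", "country")),
    "single-level")
  expect_false("gender" %in% out1$term)
  out <- respondent_effects(rec, attributes = c("country", "diving"))
  expect_equal(out$term, c("country", "diving"))
  expect_true(all(out$p >= 0 & out$p <= 1))
  expect_true(all(out$df >= 1))
})
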