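#' Split image ids into training / validation / test sets
#'
#' Shuffles ids deterministically by seed and partitions them according to
#' `fractions`, with sizes fixed by largest-remainder rounding (so 300 ids at
#' the survey's 70/15/15 protocol give exactly 210/45/45).
#'
#' @param ids Unique image ids.
#' @param fractions Length-3 positive fractions summing to 1.
#' @param seed Integer seed.
#' @return List with elements `train`, `val`, `test` (a disjoint, exhaustive
#'   partition of `ids`).
#' @export
split_dataset <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (length(fractions) != 3 || any(fractions <= 0)) {
    stop("fractions must be 3 positive numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- length(ids)
  base <- floor(n * fractions)
  frac <- n * fractions - base
  rem <- n - sum(base)
  if (rem > 0) {
    top <- order(-frac)[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  shuffled <- with_seed(seed, sample(ids))
  list(train = shuffled[seq_len(base[1])],
       val = shuffled[base[1] + seq_len(base[2])],
       test = shuffled[base[1] + base[2] + seq_len(base[3])])
}

#' Flip or rotate a square image
#'
#' `flip_image` mirrors horizontally or vertically; `rotate_image` rotates by
#' an arbitrary angle with nearest-neighbour sampling and edge-reflection
#' padding (output dimensions unchanged).
#'
#' @param pixels `S x S x 3` pixel array.
#' @param direction `"h"` (mirror columns) or `"v"` (mirror rows).
#' @return Transformed pixel array of identical dimensions.
#' @export
flip_image <- function(pixels, direction = c("h", "v")) {
  direction <- match.arg(direction)
  if (direction == "h") pixels[, rev(seq_len(dim(pixels)[2])), , drop = FALSE]
  else pixels[rev(seq_len(dim(pixels)[1])), , , drop = FALSE]
}

#' @rdname flip_image
#' @param angle Rotation angle in degrees (counter-clockwise).
#' @export
rotate_image <- function(pixels, angle) {
  s <- dim(pixels)[1]
  if (dim(pixels)[2] != s) stop("rotation requires a square image")
  if (angle %% 360 == 0) return(pixels)
  th <- angle * pi / 180
  ctr <- (s + 1) / 2
  g <- expand.grid(i = seq_len(s), j = seq_len(s))
  x <- g$j - ctr; y <- g$i - ctr
  sx <- cos(th) * x + sin(th) * y
  sy <- -sin(th) * x + cos(th) * y
  reflect <- function(k) {
    k <- ifelse(k < 1, 2 - k, k)
    k <- ifelse(k > s, 2 * s - k, k)
    pmin(pmax(round(k), 1), s)
  }
  si <- reflect(sy + ctr); sj <- reflect(sx + ctr)
  out <- pixels
  for (ch in 1:3) {
    plane <- pixels[, , ch]
    out[, , ch] <- matrix(plane[cbind(si, sj)], s, s)
  }
  out
}

#' Randomly augment a training image
#'
#' The survey protocol's augmentation set: random rotation (uniform in
#' `[-rotation_range, rotation_range]` degrees, edge reflection padding) and
#' random horizontal / vertical flips, each applied with probability 1/2.
#' Output dimensions always equal input dimensions.
#'
#' @param pixels `S x S x 3` pixel array.
#' @param augmentations Subset of `c("rotation", "hflip", "vflip")`.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @param rotation_range Half-width of the rotation angle range in degrees.
#' @return Augmented pixel array.
#' @export
augment_image <- function(pixels, augmentations = c("rotation", "hflip", "vflip"),
                          seed = NULL, rotation_range = 180) {
  bad <- setdiff(augmentations, c("rotation", "hflip", "vflip"))
  if (length(bad)) stop("unknown augmentations: ", paste(bad, collapse = ", "))
  with_seed(seed, {
    if ("rotation" %in% augmentations) {
      pixels <- rotate_image(pixels, stats::runif(1, -rotation_range, rotation_range))
    }
    if ("hflip" %in% augmentations && stats::runif(1) < 0.5) {
      pixels <- flip_image(pixels, "h")
    }
    if ("vflip" %in% augmentations && stats::runif(1) < 0.5) {
      pixels <- flip_image(pixels, "v")
    }
    pixels
  })
}

#' Configuration of the image-to-rating predictor
#'
#' Two desk-scale backends replace the original transfer-learned deep
#' network while preserving its protocol (70/15/15 split, augmentation,
#' best-epoch selection on validation loss, r-squared on the held-out test
#' set): `small_cnn`, a from-scratch convolutional regressor (two
#' convolution + average-pooling stages and two dense layers, Adam on mean
#' squared error of standardised ratings); and `linear_on_features`, an
#' ordinary least-squares fit on the nine photograph features.
#'
#' @param backend `"small_cnn"` or `"linear_on_features"`.
#' @param input_side Input image side in pixels; must satisfy the network's
#'   pooling geometry (default 64).
#' @param epochs Training epochs (>= 1).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param augmentations Subset of `c("rotation", "hflip", "vflip")` applied
#'   to each training presentation (never to validation or test).
#' @param rotation_range Rotation half-range in degrees.
#' @param n_filters1,n_filters2,n_hidden Network widths.
#' @param seed Seed for weight initialisation, shuffling and augmentation.
#' @return An object of class `predictor_config`.
#' @export
predictor_config <- function(backend = c("small_cnn", "linear_on_features"),
                             input_side = 64, epochs = 60,
                             learning_rate = 1e-3, batch_size = 16,
                             augmentations = c("rotation", "hflip", "vflip"),
                             rotation_range = 180,
                             n_filters1 = 8, n_filters2 = 24, n_hidden = 96,
                             seed = 1) {
  backend <- match.arg(backend)
  if (epochs < 1) stop("epochs must be >= 1")
  if (input_side < 16) stop("input_side must be >= 16")
  structure(list(backend = backend, input_side = input_side, epochs = epochs,
                 learning_rate = learning_rate, batch_size = batch_size,
                 augmentations = augmentations, rotation_range = rotation_range,
                 n_filters1 = n_filters1, n_filters2 = n_filters2,
                 n_hidden = n_hidden, seed = seed),
            class = "predictor_config")
}

# ---- small CNN internals -------------------------------------------------
# Architecture for side S (default 64): conv 5x5 (valid) -> ReLU -> 4x4 mean
# pool -> conv 4x4 (valid) -> ReLU -> 3x3 mean pool -> dense ReLU -> dense.
# Implemented with im2col so each layer is one BLAS matrix product.

cnn_geometry <- function(S, f1, f2, n_hidden) {
  k1 <- 5L; p1 <- 4L; k2 <- 4L; p2 <- 3L
  S1 <- S - k1 + 1L
  if (S1 %% p1 != 0) stop("input_side incompatible with network geometry")
  Sp1 <- S1 %/% p1
  S2 <- Sp1 - k2 + 1L
  if (S2 < p2 || S2 %% p2 != 0) stop("input_side incompatible with network geometry")
  Sp2 <- S2 %/% p2
  list(S = S, k1 = k1, p1 = p1, k2 = k2, p2 = p2,
       S1 = S1, Sp1 = Sp1, S2 = S2, Sp2 = Sp2,
       f1 = f1, f2 = f2, n_hidden = n_hidden,
       flat = Sp2 * Sp2 * f2,
       idx1 = im2col_index(S, k1, 3L),
       idx2 = im2col_index(Sp1, k2, f1),
       P1 = pool_matrix(S1, p1), P2 = pool_matrix(S2, p2))
}

im2col_index <- function(S, k, C) {
  So <- S - k + 1L
  pos <- expand.grid(oi = seq_len(So), oj = seq_len(So))
  off <- expand.grid(di = 0:(k - 1L), dj = 0:(k - 1L), c = seq_len(C))
  i <- outer(pos$oi, off$di, "+")
  j <- outer(pos$oj, off$dj, "+")
  cc <- matrix(off$c, nrow(pos), nrow(off), byrow = TRUE)
  idx <- i + (j - 1L) * S + (cc - 1L) * S * S
  storage.mode(idx) <- "integer"
  idx
}

pool_matrix <- function(Sin, p) {
  Sout <- Sin %/% p
  P <- matrix(0, Sout, Sin)
  for (i in seq_len(Sout)) P[i, ((i - 1L) * p + 1L):(i * p)] <- 1 / p
  P
}

cnn_init <- function(geo, seed) {
  with_seed(seed, {
    he <- function(n_in, dims) array(stats::rnorm(prod(dims), 0, sqrt(2 / n_in)), dims)
    list(W1 = he(25 * 3, c(25 * 3, geo$f1)), b1 = numeric(geo$f1),
         W2 = he(16 * geo$f1, c(16 * geo$f1, geo$f2)), b2 = numeric(geo$f2),
         W3 = he(geo$flat, c(geo$flat, geo$n_hidden)), b3 = numeric(geo$n_hidden),
         W4 = he(geo$n_hidden, c(geo$n_hidden, 1)), b4 = 0)
  })
}

# Mean-pool every channel of activation matrix A (positions x channels).
pool_all <- function(A, P, Sin) {
  Sout <- nrow(P)
  out <- matrix(0, Sout * Sout, ncol(A))
  for (ch in seq_len(ncol(A))) {
    out[, ch] <- as.vector(P %*% matrix(A[, ch], Sin, Sin) %*% t(P))
  }
  out
}

unpool_all <- function(G, P, Sin) {
  Sout <- nrow(P)
  out <- matrix(0, Sin * Sin, ncol(G))
  for (ch in seq_len(ncol(G))) {
    out[, ch] <- as.vector(t(P) %*% matrix(G[, ch], Sout, Sout) %*% P)
  }
  out
}

cnn_forward <- function(x, par, geo, keep = FALSE) {
  X1 <- matrix(x[geo$idx1], nrow = nrow(geo$idx1))
  Z1 <- sweep(X1 %*% par$W1, 2, par$b1, "+")
  A1 <- pmax(Z1, 0)
  A1p <- pool_all(A1, geo$P1, geo$S1)
  X2 <- matrix(as.vector(A1p)[geo$idx2], nrow = nrow(geo$idx2))
  Z2 <- sweep(X2 %*% par$W2, 2, par$b2, "+")
  A2 <- pmax(Z2, 0)
  A2p <- pool_all(A2, geo$P2, geo$S2)
  f <- as.vector(A2p)
  z3 <- drop(f %*% par$W3) + par$b3
  h <- pmax(z3, 0)
  y <- drop(h %*% par$W4) + par$b4
  if (!keep) return(y)
  list(y = y, X1 = X1, Z1 = Z1, X2 = X2, Z2 = Z2, f = f, z3 = z3, h = h)
}

# Gradient of 0.5 * (y - t)^2 with respect to all parameters.
cnn_backward <- function(cache, t, par, geo) {
  g <- cache$y - t
  dW4 <- matrix(cache$h * g, ncol = 1)
  db4 <- g
  dh <- drop(par$W4) * g
  dh[cache$z3 <= 0] <- 0
  dW3 <- outer(cache$f, dh)
  db3 <- dh
  df <- drop(par$W3 %*% dh)
  dA2p <- matrix(df, ncol = geo$f2)
  dA2 <- unpool_all(dA2p, geo$P2, geo$S2)
  dZ2 <- dA2 * (cache$Z2 > 0)
  dW2 <- crossprod(cache$X2, dZ2)
  db2 <- colSums(dZ2)
  dX2 <- tcrossprod(dZ2, par$W2)
  dx2 <- scatter_sum(dX2, geo$idx2, geo$Sp1 * geo$Sp1 * geo$f1)
  dA1p <- matrix(dx2, ncol = geo$f1)
  dA1 <- unpool_all(dA1p, geo$P1, geo$S1)
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- crossprod(cache$X1, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

scatter_sum <- function(G, idx, n) {
  rs <- rowsum(as.vector(G), group = as.vector(idx))
  out <- numeric(n)
  out[as.integer(rownames(rs))] <- rs
  out
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(par)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grad[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grad[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

# ---- training ------------------------------------------------------------

image_getter <- function(images) {
  if (is.function(images)) return(images)
  if (is.null(names(images))) stop("images must be a named list or a loader function")
  function(id) {
    img <- images[[id]]
    if (is.null(img)) stop("missing image for id: ", id)
    if (inherits(img, "quadrat_image")) img$pixels else img
  }
}

prep_input <- function(pixels, side) {
  standardize_image(pixels, target_side = side) / 255
}

ratings_vector <- function(ratings) {
  if (is.data.frame(ratings)) {
    stats::setNames(ratings$rating_mean, ratings$image_id)
  } else {
    ratings
  }
}

#' Train the image-to-rating predictor
#'
#' Trains on the training ids only (validation images are used for loss
#' monitoring, never for gradient updates; test images are never read), with
#' per-presentation augmentation, and returns the parameter state achieving
#' the best validation loss across epochs. Fully deterministic given
#' `config$seed`.
#'
#' @param images Named list of [quadrat_image()] / pixel arrays, or a loader
#'   `function(id)` returning a pixel array.
#' @param ratings An `elo_ratings` data.frame or named numeric vector of
#'   aesthetic ratings.
#' @param train_ids,val_ids Image ids of the training and validation sets.
#' @param config A [predictor_config()].
#' @param features For the `linear_on_features` backend: a data.frame with
#'   `image_id` and numeric feature columns.
#' @return An object of class `reef_predictor` with the best-epoch
#'   parameters, the training history (`epoch`, `train_loss`, `val_loss`)
#'   and the rating standardisation constants.
#' @export
train_predictor <- function(images, ratings, train_ids, val_ids,
                            config = predictor_config(), features = NULL) {
  if (length(train_ids) == 0) stop("empty training set")
  y <- ratings_vector(ratings)
  missing_y <- setdiff(c(train_ids, val_ids), names(y))
  if (length(missing_y)) {
    stop("no rating for ids: ", paste(utils::head(missing_y, 5), collapse = ", "))
  }
  if (config$backend == "linear_on_features") {
    return(train_linear_features(features, y, train_ids, val_ids, config))
  }
  get <- image_getter(images)
  side <- config$input_side
  geo <- cnn_geometry(side, config$n_filters1, config$n_filters2, config$n_hidden)
  x_train <- lapply(train_ids, function(id) prep_input(get(id), side))
  x_val <- lapply(val_ids, function(id) prep_input(get(id), side))
  y_mean <- mean(y[train_ids]); y_sd <- stats::sd(y[train_ids])
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  yt <- (y[train_ids] - y_mean) / y_sd
  yv <- (y[val_ids] - y_mean) / y_sd
  par <- cnn_init(geo, substream_seed(config$seed, "cnn_init"))
  opt <- adam_init(par)
  best <- list(par = par, val = Inf, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  val_loss_fn <- function(par) {
    if (length(x_val) == 0) return(NA_real_)
    preds <- vapply(x_val, function(x) cnn_forward(as.vector(x), par, geo),
                    numeric(1))
    mean((preds - yv)^2)
  }
  with_seed(substream_seed(config$seed, "cnn_train"), {
    n <- length(x_train)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      train_loss <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1, n)]
        grad <- NULL
        for (i in batch) {
          x <- x_train[[i]]
          if (length(config$augmentations)) {
            x <- augment_image(x, config$augmentations,
                               rotation_range = config$rotation_range)
          }
          cache <- cnn_forward(as.vector(x), par, geo, keep = TRUE)
          gi <- cnn_backward(cache, yt[i], par, geo)
          train_loss <- train_loss + 0.5 * (cache$y - yt[i])^2
          grad <- if (is.null(grad)) gi else Map(`+`, grad, gi)
        }
        grad <- lapply(grad, function(g) g / length(batch))
        upd <- adam_step(par, grad, opt, config$learning_rate)
        par <- upd$par; opt <- upd$state
      }
      vl <- val_loss_fn(par)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = train_loss / n,
                                           val_loss = vl))
      if (is.na(vl) || vl < best$val) {
        best <- list(par = par, val = if (is.na(vl)) Inf else vl, epoch = epoch)
      }
    }
  })
  structure(list(backend = "small_cnn", par = best$par, geometry_seed = side,
                 config = config, y_mean = y_mean, y_sd = y_sd,
                 history = history, best_epoch = best$epoch,
                 train_ids = train_ids, val_ids = val_ids),
            class = "reef_predictor")
}

train_linear_features <- function(features, y, train_ids, val_ids, config) {
  if (is.null(features)) {
    stop("linear_on_features backend requires a feature table")
  }
  num_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  X <- features[match(train_ids, features$image_id), num_cols, drop = FALSE]
  fit <- stats::lm(y ~ ., data = cbind(y = unname(y[train_ids]), X))
  structure(list(backend = "linear_on_features", fit = fit,
                 feature_cols = num_cols, features = features,
                 config = config, y_mean = 0, y_sd = 1,
                 history = NULL, best_epoch = 1L,
                 train_ids = train_ids, val_ids = val_ids),
            class = "reef_predictor")
}

#' Predict aesthetic ratings for a set of images
#'
#' @param model A trained [train_predictor()] model.
#' @param images Named list of images or a loader `function(id)` (ignored by
#'   the `linear_on_features` backend, which uses its feature table).
#' @param ids Ids to predict; defaults to `names(images)`.
#' @return Named numeric vector of predicted ratings, one finite value per
#'   id, on the original rating scale. Deterministic.
#' @export
predict_ratings <- function(model, images = NULL, ids = NULL) {
  stopifnot(inherits(model, "reef_predictor"))
  if (model$backend == "linear_on_features") {
    feats <- model$features
    if (is.null(ids)) ids <- feats$image_id
    X <- feats[match(ids, feats$image_id), model$feature_cols, drop = FALSE]
    if (anyNA(match(ids, feats$image_id))) {
      stop("missing features for ids: ",
           paste(utils::head(ids[is.na(match(ids, feats$image_id))], 5),
                 collapse = ", "))
    }
    return(stats::setNames(as.numeric(stats::predict(model$fit, newdata = X)), ids))
  }
  get <- image_getter(images)
  if (is.null(ids)) {
    if (is.function(images)) stop("ids must be given with a loader function")
    ids <- names(images)
  }
  cfg <- model$config
  geo <- cnn_geometry(cfg$input_side, cfg$n_filters1, cfg$n_filters2, cfg$n_hidden)
  preds <- vapply(ids, function(id) {
    x <- prep_input(get(id), cfg$input_side)
    cnn_forward(as.vector(x), model$par, geo)
  }, numeric(1))
  stats::setNames(preds * model$y_sd + model$y_mean, ids)
}

#' Squared Pearson correlation between predictions and observations
#'
#' The accuracy metric of the rating predictor: the r-squared of the linear
#' regression between predicted and held-out observed ratings. Errors on
#' degenerate inputs (fewer than 3 points, or constant predictions, where
#' the correlation is undefined); warns when predictions are anti-correlated
#' with the observations, since the squared correlation alone would hide the
#' sign.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return Squared Pearson correlation in `[0, 1]`.
#' @export
evaluate_r2 <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) < 3) stop("need at least 3 points to estimate r-squared")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("correlation undefined: constant predictions or observations")
  }
  r <- stats::cor(predicted, observed)
  if (r < 0) warning(sprintf("predictions are anti-correlated with observations (r = %.3f)", r))
  r^2
}

#' @export
print.reef_predictor <- function(x, ...) {
  cat(sprintf("<reef_predictor> backend=%s best_epoch=%d train_n=%d\n",
              x$backend, x$best_epoch, length(x$train_ids)))
  invisible(x)
}
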