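#' Remove collinear features by the correlation-threshold rule
#'
#' Iteratively screens the feature set before regression: while any feature
#' pair has absolute Pearson correlation above `threshold` (0.7 in the
#' original analysis), the most-correlated offending pair is examined and
#' the member with the *lower* absolute correlation to the target is
#' dropped. Constant features (undefined correlation) are dropped up front
#' with a warning. Every removal is logged with both correlations.
#'
#' @param features data.frame (or matrix) of numeric feature columns.
#' @param target Numeric response (the predicted aesthetic rating).
#' @param threshold Absolute pairwise correlation threshold (default 0.7).
#' @return List of class `correlation_filter`: `retained` (feature names),
#'   `removals` (log data.frame with `dropped`, `kept`, `r_pair`,
#'   `r_dropped_target`, `r_kept_target`), `cor_target`.
#' @export
correlation_filter <- function(features, target, threshold = 0.7) {
  features <- as.data.frame(features)
  if (ncol(features) < 2) stop("need at least 2 features")
  if (nrow(features) != length(target)) stop("features/target length mismatch")
  sds <- vapply(features, stats::sd, numeric(1))
  removals <- data.frame(dropped = character(0), kept = character(0),
                         r_pair = numeric(0), r_dropped_target = numeric(0),
                         r_kept_target = numeric(0), stringsAsFactors = FALSE)
  if (any(sds == 0 | is.na(sds))) {
    const <- names(features)[sds == 0 | is.na(sds)]
    warning("dropping constant features (correlation undefined): ",
            paste(const, collapse = ", "))
    removals <- rbind(removals, data.frame(
      dropped = const, kept = NA_character_, r_pair = NA_real_,
      r_dropped_target = NA_real_, r_kept_target = NA_real_))
    features <- features[, setdiff(names(features), const), drop = FALSE]
  }
  r_target <- vapply(features, function(x) stats::cor(x, target), numeric(1))
  keep <- names(features)
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(features[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    pair <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- keep[pair[1]]; b <- keep[pair[2]]
    # keep the feature more correlated to the target; ties keep the
    # alphabetically first name (deterministic)
    drop_b <- abs(r_target[b]) < abs(r_target[a]) ||
      (abs(r_target[b]) == abs(r_target[a]) && b > a)
    dropped <- if (drop_b) b else a
    kept <- if (drop_b) a else b
    removals <- rbind(removals, data.frame(
      dropped = dropped, kept = kept, r_pair = stats::cor(features[[a]], features[[b]]),
      r_dropped_target = unname(r_target[dropped]),
      r_kept_target = unname(r_target[kept]), stringsAsFactors = FALSE))
    keep <- setdiff(keep, dropped)
  }
  structure(list(retained = keep, removals = removals,
                 cor_target = r_target[keep], threshold = threshold),
            class = "correlation_filter")
}

#' Backward stepwise elimination of non-significant features
#'
#' Ordinary least squares on unit-variance-scaled features against the
#' unscaled response, repeatedly refitting after removing the single feature
#' with the largest p-value above `alpha` (0.05 in the original analysis),
#' until every retained feature is significant. Ties in the maximal p-value
#' are broken by dropping the alphabetically first name.
#'
#' @param features data.frame of numeric feature columns (screened by
#'   [correlation_filter()] upstream).
#' @param response Numeric response, kept unscaled.
#' @param alpha Significance threshold for retention.
#' @return List of class `stepwise_fit`: `retained`, `coefficients` (scaled
#'   estimate, SE, t, p per retained feature), `r_squared`, `model` (the
#'   final `lm`), `eliminated` (in removal order).
#' @export
backward_stepwise <- function(features, response, alpha = 0.05) {
  features <- as.data.frame(features)
  scaled <- as.data.frame(scale(features))
  keep <- sort(names(scaled))
  eliminated <- character(0)
  fit <- NULL
  repeat {
    if (length(keep) == 0) {
      warning("no feature survives backward elimination; returning empty model")
      fit <- stats::lm(response ~ 1)
      break
    }
    dat <- cbind(.response = response, scaled[, keep, drop = FALSE])
    fit <- stats::lm(.response ~ ., data = dat)
    coefs <- summary(fit)$coefficients
    pv <- coefs[setdiff(rownames(coefs), "(Intercept)"), "Pr(>|t|)"]
    names(pv) <- setdiff(rownames(coefs), "(Intercept)")
    if (all(pv <= alpha)) break
    worst <- names(pv)[pv == max(pv)]
    worst <- sort(worst)[1]
    keep <- setdiff(keep, worst)
    eliminated <- c(eliminated, worst)
  }
  coefs <- summary(fit)$coefficients
  rows <- setdiff(rownames(coefs), "(Intercept)")
  structure(list(
    retained = keep,
    coefficients = data.frame(
      feature = rows,
      estimate = coefs[rows, "Estimate"],
      std_error = coefs[rows, "Std. Error"],
      t_value = coefs[rows, "t value"],
      p_value = coefs[rows, "Pr(>|t|)"],
      row.names = NULL, stringsAsFactors = FALSE),
    r_squared = summary(fit)$r.squared,
    model = fit, eliminated = eliminated, alpha = alpha),
    class = "stepwise_fit")
}

#' Per-feature share of explained variance (LMG decomposition)
#'
#' Decomposes the regression's explained variance into per-feature
#' percentages by the LMG method: each feature's sequential R-squared
#' increment, averaged over all orderings of feature entry, normalised to
#' sum to 100. Exact over all orderings (computed by the all-subsets
#' identity); refuses more than 10 features. The simpler
#' squared-standardised-coefficient decomposition is available as an
#' alternative.
#'
#' @param features data.frame of numeric feature columns (the retained set
#'   from [backward_stepwise()]).
#' @param response Numeric response.
#' @param method `"lmg"` (default) or `"betasq"`.
#' @return Named numeric percentages summing to 100, with attribute
#'   `method` and `total_r_squared`.
#' @export
importance_shares <- function(features, response, method = c("lmg", "betasq")) {
  method <- match.arg(method)
  features <- as.data.frame(features)
  p <- ncol(features)
  if (p == 0) stop("no features")
  nms <- names(features)
  if (p == 1) {
    out <- stats::setNames(100, nms)
    attr(out, "method") <- method
    attr(out, "total_r_squared") <- summary(
      stats::lm(response ~ ., data = features))$r.squared
    return(out)
  }
  if (method == "betasq") {
    fit <- stats::lm(response ~ ., data = as.data.frame(scale(features)))
    b2 <- stats::coef(fit)[-1]^2
    out <- 100 * b2 / sum(b2)
    names(out) <- nms
    attr(out, "method") <- "betasq"
    attr(out, "total_r_squared") <- summary(fit)$r.squared
    return(out)
  }
  if (p > 10) {
    stop("LMG over more than 10 features is factorially expensive; ",
         "use method = 'betasq' or sample orderings externally")
  }
  # R^2 of every subset, indexed by bitmask
  r2 <- numeric(2^p)
  for (mask in 1:(2^p - 1)) {
    cols <- nms[bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L]
    dat <- cbind(.response = response, features[, cols, drop = FALSE])
    r2[mask + 1L] <- summary(stats::lm(.response ~ ., data = dat))$r.squared
  }
  fact <- factorial(0:p)
  lmg <- numeric(p)
  for (j in seq_len(p)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(2^p - 1)) {
      if (bitwAnd(mask, bit_j) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      w <- fact[s + 1] * fact[p - s] / fact[p + 1] # |S|! (p-|S|-1)! / p!
      lmg[j] <- lmg[j] + w * (r2[bitwOr(mask, bit_j) + 1L] - r2[mask + 1L])
    }
  }
  out <- 100 * lmg / sum(lmg)
  names(out) <- nms
  attr(out, "method") <- "lmg"
  attr(out, "total_r_squared") <- r2[2^p]
  out
}
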