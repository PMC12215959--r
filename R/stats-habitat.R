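#' Mixed-model comparison of a response across habitats
#'
#' Fits `value ~ habitat + (1 | site_id)` with the family appropriate to the
#' response (Gaussian LMM for ratings and percent covers; Gamma with log
#' link for positive skewed responses such as the Simpson index and percent
#' blue; Poisson for the colour and morphology counts) and tests the habitat
#' effect by a likelihood-ratio ANOVA against the null model without the
#' fixed term. The LRT uses maximum-likelihood fits; for the Gaussian case
#' the reported parameter estimates are refit by REML. Gamma responses of
#' exactly 0 are nudged to the smallest representable positive value (the
#' Gamma support excludes 0) and the nudge is recorded. Singular random-
#' effect fits are flagged in the result, not silently ignored.
#'
#' @param data data.frame with columns `value`, `habitat`, `site_id` (or
#'   give `response` to pick another value column).
#' @param family `"gaussian"`, `"gamma_log"` or `"poisson"`.
#' @param response Optional name of the value column (default `"value"`).
#' @return List of class `habitat_test`: `response`, `family`, `chi2`, `df`,
#'   `p`, `fit` (model for post-hoc work), `singular`, `n_nudged`.
#' @seealso [tukey_posthoc()]
#' @export
fit_habitat_model <- function(data, family = c("gaussian", "gamma_log", "poisson"),
                              response = "value") {
  family <- match.arg(family)
  stopifnot(all(c(response, "habitat", "site_id") %in% names(data)))
  d <- data.frame(value = data[[response]],
                  habitat = factor(data$habitat),
                  site_id = factor(data$site_id))
  if (anyNA(d$value)) stop("response contains NA")
  per_hab <- tapply(d$site_id, d$habitat, function(s) length(unique(s)))
  if (any(per_hab < 2)) {
    warning("fewer than 2 sites in some habitat; random-effect variance is weakly identified")
  }
  n_nudged <- 0L
  if (family == "gamma_log") {
    if (any(d$value < 0)) stop("Gamma family requires non-negative values")
    n_nudged <- sum(d$value == 0)
    if (n_nudged > 0) {
      # Gamma support excludes 0: nudge zeros to half the smallest positive
      # observation (a machine-epsilon floor puts log-link fits ~36 log
      # units below the data and breaks convergence)
      pos <- d$value[d$value > 0]
      floor_val <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
      d$value <- pmax(d$value, floor_val)
    }
  }
  if (family == "poisson" && any(d$value != round(d$value))) {
    stop("Poisson family requires integer counts")
  }
  if (stats::sd(d$value) == 0) {
    # degenerate input: no variance, no testable effect
    return(structure(list(response = response, family = family,
                          chi2 = 0, df = nlevels(d$habitat) - 1L, p = 1,
                          fit = NULL, singular = TRUE, n_nudged = n_nudged,
                          data = d),
                     class = "habitat_test"))
  }
  if (family == "gaussian") {
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
    full_ml <- lme4::lmer(value ~ habitat + (1 | site_id), data = d,
                          REML = FALSE, control = ctrl)
    null_ml <- lme4::lmer(value ~ 1 + (1 | site_id), data = d,
                          REML = FALSE, control = ctrl)
    fit <- lme4::lmer(value ~ habitat + (1 | site_id), data = d,
                      REML = TRUE, control = ctrl)
  } else {
    fam <- if (family == "gamma_log") stats::Gamma(link = "log") else stats::poisson()
    ctrl <- lme4::glmerControl(check.conv.singular = "ignore")
    full_ml <- suppressWarnings(
      lme4::glmer(value ~ habitat + (1 | site_id), data = d, family = fam,
                  control = ctrl))
    null_ml <- suppressWarnings(
      lme4::glmer(value ~ 1 + (1 | site_id), data = d, family = fam,
                  control = ctrl))
    fit <- full_ml
  }
  lrt <- stats::anova(null_ml, full_ml)
  structure(list(response = response, family = family,
                 chi2 = lrt$Chisq[2], df = lrt$Df[2],
                 p = lrt$`Pr(>Chisq)`[2],
                 fit = fit, singular = lme4::isSingular(full_ml),
                 n_nudged = n_nudged, data = d),
            class = "habitat_test")
}

#' @export
print.habitat_test <- function(x, ...) {
  cat(sprintf("<habitat_test> %s (%s): chi2 = %.3f, df = %d, p = %.4g%s\n",
              x$response, x$family, x$chi2, x$df, x$p,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Tukey HSD post-hoc habitat contrasts with compact letters
#'
#' All pairwise habitat contrasts on the fitted mixed model's estimated
#' habitat means (link scale for GLMMs), with family-wise adjustment by the
#' studentized-range (Tukey) distribution, and a compact letter display:
#' habitats sharing a letter are not significantly different. For the
#' Gaussian LMM the reference degrees of freedom are the between-site
#' residual df (sites minus habitat levels, the effective replication);
#' GLMM contrasts use the normal reference (`df = Inf`).
#'
#' @param x A `habitat_test` from [fit_habitat_model()].
#' @param alpha Significance level for the letter display.
#' @return List of class `tukey_posthoc`: `contrasts` (data.frame with
#'   estimate, SE, z, adjusted p per habitat pair) and `letters` (named
#'   character per habitat).
#' @export
tukey_posthoc <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "habitat_test"))
  levs <- levels(x$data$habitat)
  k <- length(levs)
  if (is.null(x$fit)) { # degenerate constant-response case: no differences
    letters <- stats::setNames(rep("a", k), levs)
    contrasts <- data.frame(contrast = apply(utils::combn(levs, 2), 2,
                                             paste, collapse = " - "),
                            estimate = 0, std_error = NA_real_, z = 0,
                            p_adj = 1, stringsAsFactors = FALSE)
    return(structure(list(contrasts = contrasts, letters = letters,
                          alpha = alpha), class = "tukey_posthoc"))
  }
  beta <- lme4::fixef(x$fit)
  V <- as.matrix(stats::vcov(x$fit))
  # design rows for each habitat mean under treatment coding
  M <- matrix(0, k, length(beta), dimnames = list(levs, names(beta)))
  M[, "(Intercept)"] <- 1
  for (l in levs[-1]) M[l, paste0("habitat", l)] <- 1
  pairs <- utils::combn(levs, 2)
  K <- t(apply(pairs, 2, function(pr) M[pr[1], ] - M[pr[2], ]))
  est <- drop(K %*% beta)
  se <- sqrt(diag(K %*% V %*% t(K)))
  z <- est / se
  df <- if (x$family == "gaussian") {
    max(nlevels(x$data$site_id) - k, 1)
  } else {
    Inf
  }
  p_adj <- 1 - stats::ptukey(sqrt(2) * abs(z), nmeans = k, df = df)
  contrasts <- data.frame(
    contrast = apply(pairs, 2, paste, collapse = " - "),
    estimate = est, std_error = se, z = z, p_adj = p_adj,
    stringsAsFactors = FALSE)
  structure(list(contrasts = contrasts,
                 letters = compact_letters(levs, pairs, p_adj, alpha),
                 alpha = alpha),
            class = "tukey_posthoc")
}

# Compact letter display: letters are maximal cliques of the
# "not significantly different" graph (insert-and-absorb for small k).
compact_letters <- function(levs, pairs, p_adj, alpha) {
  k <- length(levs)
  ns <- matrix(TRUE, k, k, dimnames = list(levs, levs))
  for (i in seq_len(ncol(pairs))) {
    if (p_adj[i] < alpha) {
      ns[pairs[1, i], pairs[2, i]] <- FALSE
      ns[pairs[2, i], pairs[1, i]] <- FALSE
    }
  }
  # enumerate maximal cliques by subset scan (k is 3 here; fine to k ~ 12)
  cliques <- list()
  for (mask in 1:(2^k - 1)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    if (all(ns[members, members])) cliques[[length(cliques) + 1]] <- members
  }
  is_max <- vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(cl)
      length(cl) > length(cliques[[i]]) && all(cliques[[i]] %in% cl),
      logical(1)))
  }, logical(1))
  cliques <- cliques[is_max]
  ord <- order(vapply(cliques, min, numeric(1)))
  cliques <- cliques[ord]
  out <- stats::setNames(rep("", k), levs)
  for (i in seq_along(cliques)) {
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  }
  out
}

#' @export
print.tukey_posthoc <- function(x, ...) {
  cat("<tukey_posthoc>\n")
  print(x$contrasts, row.names = FALSE)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
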