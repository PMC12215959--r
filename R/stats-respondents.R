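#' Test socio-cultural effects on pairwise choices
#'
#' Binomial GLMM on the forced-choice records: the response is whether the
#' first-presented photograph won, the respondent's socio-cultural
#' attributes enter as fixed effects, and the photograph enters as a random
#' intercept (both presented photos get one). Each attribute is tested by a
#' likelihood-ratio drop-one comparison (analysis of deviance). Under the
#' survey's null finding no attribute should be significant; an injected
#' attribute effect in [simulate_choices()] is detectable here.
#'
#' @param records Preference records with attribute columns (from
#'   [simulate_choices()], after [exclude_colour_deficient()]).
#' @param attributes Attribute columns to test; defaults to the six
#'   socio-cultural variables.
#' @param interactions If `TRUE`, additionally test all two-way interactions
#'   among the retained attributes (slow).
#' @param nAGQ Integrator passed to [lme4::glmer()]; 0 uses the fast
#'   Laplace-free approximation, adequate for screening and simulation.
#' @return data.frame of class `respondent_effects`: `term`, `chisq`, `df`,
#'   `p`.
#' @export
respondent_effects <- function(records,
                               attributes = c("gender", "age_class", "country",
                                              "education", "diving",
                                              "coral_knowledge"),
                               interactions = FALSE, nAGQ = 0L) {
  if (nrow(records) == 0) stop("no records")
  present <- intersect(attributes, names(records))
  if (length(present) == 0) stop("records carry none of the requested attributes")
  d <- data.frame(win_a = as.integer(records$winner == records$photo_a),
                  photo_a = factor(records$photo_a),
                  photo_b = factor(records$photo_b))
  for (a in present) d[[a]] <- factor(records[[a]])
  n_levels <- vapply(present, function(a) nlevels(d[[a]]), integer(1))
  if (any(n_levels < 2)) {
    warning("dropping single-level attributes: ",
            paste(present[n_levels < 2], collapse = ", "))
    present <- present[n_levels >= 2]
  }
  if (length(present) == 0) stop("no attribute with at least 2 levels to test")
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore")
  fit_glmm <- function(fixed_terms) {
    rhs <- paste(c(fixed_terms, "1", "(1 | photo_a)", "(1 | photo_b)"),
                 collapse = " + ")
    suppressWarnings(lme4::glmer(
      stats::as.formula(paste("win_a ~", rhs)), data = d,
      family = stats::binomial(), nAGQ = nAGQ, control = ctrl))
  }
  drop_one <- function(terms) {
    full <- fit_glmm(terms)
    rows <- lapply(terms, function(tm) {
      reduced <- fit_glmm(setdiff(terms, tm))
      lrt <- stats::anova(reduced, full)
      data.frame(term = tm, chisq = lrt$Chisq[2], df = lrt$Df[2],
                 p = lrt$`Pr(>Chisq)`[2], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  # main effects tested within the mains-only model; two-way interactions
  # (if requested) tested by drop-one from the model with all interactions
  out <- drop_one(present)
  if (interactions) {
    inter <- utils::combn(present, 2, paste, collapse = ":")
    full_terms <- c(present, inter)
    full <- fit_glmm(full_terms)
    irows <- lapply(inter, function(tm) {
      reduced <- fit_glmm(setdiff(full_terms, tm))
      lrt <- stats::anova(reduced, full)
      data.frame(term = tm, chisq = lrt$Chisq[2], df = lrt$Df[2],
                 p = lrt$`Pr(>Chisq)`[2], stringsAsFactors = FALSE)
    })
    out <- rbind(out, do.call(rbind, irows))
  }
  class(out) <- c("respondent_effects", "data.frame")
  out
}
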