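#' Vocabularies of the respondent socio-cultural attributes
#'
#' @return Named list of level vectors for gender, age class (ordered),
#'   country, education (ordered), diving experience and self-declared coral
#'   knowledge (ordered).
#' @export
respondent_vocab <- function() {
  list(
    gender = c("female", "male", "other"),
    age_class = c("<12", "13-18", "19-39", "40-59", ">60"),
    country = c("France", "Indonesia", "UK", "USA", "Australia", "Other"),
    education = c("secondary", "high_school", "bachelor", "master", "phd"),
    diving = c("diving", "snorkelling", "none"),
    coral_knowledge = c("poor", "low", "average", "good", "excellent")
  )
}

# Marginal attribute frequencies emulating the survey population: country,
# education, coral knowledge and diving follow the published respondent
# breakdown; gender and age splits are not published and use broad defaults.
respondent_probs <- function() {
  list(
    gender = c(0.52, 0.45, 0.03),
    age_class = c(0.01, 0.05, 0.55, 0.29, 0.10),
    country = c(0.285, 0.162, 0.140, 0.099, 0.071, 0.243),
    education = c(0.0481, 0.1039, 0.2772, 0.3235, 0.2473),
    diving = c(0.5332, 0.2437, 0.2231),
    coral_knowledge = c(0.1266, 0.2506, 0.2628, 0.2318, 0.1281)
  )
}

#' Simulate survey respondents with socio-cultural attributes
#'
#' Draws respondents with attributes from the survey population's marginal
#' frequencies. Colour-vision deficiency is flagged at the survey's observed
#' rate (96 of 3,348 respondents) by default; flagged respondents are removed
#' by [exclude_colour_deficient()] before rating.
#'
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @param p_colour_deficient Probability of the colour-deficiency flag.
#' @return A data.frame with one row per respondent: `respondent_id`, the
#'   six attribute columns and `colour_deficiency`.
#' @export
simulate_respondents <- function(n, seed = 1, p_colour_deficient = 96 / 3348) {
  stopifnot(n >= 1)
  vocab <- respondent_vocab()
  probs <- respondent_probs()
  with_seed(seed, {
    out <- data.frame(respondent_id = sprintf("r%05d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (a in names(vocab)) {
      out[[a]] <- sample(vocab[[a]], n, replace = TRUE, prob = probs[[a]])
    }
    out$colour_deficiency <- stats::runif(n) < p_colour_deficient
    out
  })
}

#' Elo / logistic win probability from a rating or score gap
#'
#' `P(a beats b) = 1 / (1 + 10^((s_b - s_a) / 400))`: a 400-point advantage
#' wins with probability 10/11, equal scores win 50%.
#'
#' @param s_a,s_b Scores (or ratings) of the two contestants.
#' @return Probability that `a` is chosen.
#' @export
elo_win_prob <- function(s_a, s_b) {
  1 / (1 + 10^((s_b - s_a) / 400))
}

#' Simulate pairwise aesthetic choices from latent scores
#'
#' Each respondent sees `pairs_each` distinct random photo pairs (30 in the
#' survey protocol) and must choose one of the two (forced choice, no ties).
#' The choice follows the Elo-consistent logistic rule on the latent score
#' gap. Optional attribute effects shift the effective score of the
#' first-presented photo for respondents carrying the attribute level,
#' injecting a detectable socio-cultural signal; the default (`NULL`) injects
#' nothing, mirroring the survey's null finding.
#'
#' @param scores Named numeric: latent (or true) aesthetic score per
#'   image id. At least 2 images.
#' @param n_respondents Number of simulated respondents (ignored when
#'   `respondents` is supplied).
#' @param pairs_each Pairs shown per respondent (default 30).
#' @param attr_effects Optional named list: attribute name -> named numeric
#'   of per-level score shifts (rating points) applied to `photo_a`.
#' @param respondents Optional pre-built respondent table from
#'   [simulate_respondents()].
#' @param seed Integer seed.
#' @return A data.frame of preference records: `respondent_id`, `photo_a`,
#'   `photo_b`, `winner`, plus the respondent attribute columns.
#' @export
simulate_choices <- function(scores, n_respondents, pairs_each = 30,
                             attr_effects = NULL, respondents = NULL,
                             seed = 1) {
  if (length(scores) < 2) stop("need at least 2 images to form pairs")
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("scores must be uniquely named by image id")
  }
  ids <- names(scores)
  n_pairs_total <- choose(length(ids), 2)
  if (pairs_each > n_pairs_total) {
    stop("pairs_each exceeds the number of distinct pairs available")
  }
  if (is.null(respondents)) {
    respondents <- simulate_respondents(n_respondents,
                                        seed = substream_seed(seed, "respondents"))
  }
  n_resp <- nrow(respondents)
  with_seed(substream_seed(seed, "choices"), {
    rows <- vector("list", n_resp)
    for (i in seq_len(n_resp)) {
      # distinct unordered pairs within a respondent; presentation order random
      pair_keys <- integer(0)
      a_idx <- b_idx <- integer(0)
      while (length(pair_keys) < pairs_each) {
        need <- pairs_each - length(pair_keys)
        p1 <- sample.int(length(ids), 2 * need, replace = TRUE)
        p2 <- sample.int(length(ids), 2 * need, replace = TRUE)
        ok <- p1 != p2
        p1 <- p1[ok]; p2 <- p2[ok]
        key <- pmin(p1, p2) * (length(ids) + 1L) + pmax(p1, p2)
        keep <- !duplicated(key) & !key %in% pair_keys
        take <- which(keep)[seq_len(min(need, sum(keep)))]
        pair_keys <- c(pair_keys, key[take])
        a_idx <- c(a_idx, p1[take]); b_idx <- c(b_idx, p2[take])
      }
      shift <- attr_shift(respondents[i, ], attr_effects)
      p_a <- elo_win_prob(scores[a_idx] + shift, scores[b_idx])
      a_wins <- stats::runif(pairs_each) < p_a
      rows[[i]] <- data.frame(
        respondent_id = respondents$respondent_id[i],
        photo_a = ids[a_idx], photo_b = ids[b_idx],
        winner = ifelse(a_wins, ids[a_idx], ids[b_idx]),
        stringsAsFactors = FALSE
      )
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    merge_attrs(records, respondents)
  })
}

attr_shift <- function(resp_row, attr_effects) {
  if (is.null(attr_effects)) return(0)
  total <- 0
  for (a in names(attr_effects)) {
    lev <- as.character(resp_row[[a]])
    eff <- attr_effects[[a]]
    if (!is.null(eff) && lev %in% names(eff)) total <- total + eff[[lev]]
  }
  total
}

merge_attrs <- function(records, respondents) {
  out <- merge(records, respondents, by = "respondent_id", sort = FALSE)
  out[order(match(out$respondent_id, respondents$respondent_id)), , drop = FALSE]
}

#' Exclude records from colour-vision-deficient respondents
#'
#' Mirrors the survey rule: responses from participants reporting problems
#' with colour perception are removed before any rating.
#'
#' @param records Preference records with a `colour_deficiency` column.
#' @return The surviving records, original order preserved.
#' @export
exclude_colour_deficient <- function(records) {
  if (!"colour_deficiency" %in% names(records)) {
    stop("records must carry respondent attributes (colour_deficiency column)")
  }
  out <- records[!records$colour_deficiency, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("all respondents reported colour-vision deficiency; no records remain")
  }
  rownames(out) <- NULL
  out
}
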