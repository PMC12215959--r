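#' Configuration of a full desk-scale synthetic study
#'
#' Defaults reproduce the survey's bookkeeping: 6 sites per habitat times 50
#' photos per site (900 photographs), a QC discard probability of 17/900, a
#' survey subset of 100 photos per habitat (300 total) and 30 pairwise
#' choices per respondent. The respondent count (3,348 in the original
#' survey) is scaled to 200 at desk scale; image side is 64 px, the
#' predictor's input size.
#'
#' @param n_sites_per_habitat Sites per habitat condition.
#' @param photos_per_site Photographs per site.
#' @param survey_subset_per_habitat Photos per habitat entering the survey.
#' @param n_respondents Simulated survey respondents.
#' @param pairs_each Pairwise choices per respondent.
#' @param qc_fail_prob Probability a photo fails the colour-card QC check.
#' @param image_side Generated image side length (pixels).
#' @param site_cover_sd Between-site SD of the coral-cover mean (percentage
#'   points); gives the site random intercept its variance.
#' @param latent_noise_sd Noise SD of the latent aesthetic score (rating
#'   points).
#' @param latent_weights Ground-truth feature weights, see [latent_score()].
#' @param attr_effects Optional injected socio-cultural effects, see
#'   [simulate_choices()].
#' @param elo An [elo_config()].
#' @param predictor A [predictor_config()].
#' @param run_respondent_test Run the socio-cultural GLMM (slowest stage).
#' @param n_points Point-intercept points per photo.
#' @param seed Master seed; every stage draws from a named substream.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_sites_per_habitat = 6, photos_per_site = 50,
                         survey_subset_per_habitat = 100,
                         n_respondents = 400, pairs_each = 30,
                         qc_fail_prob = 17 / 900, image_side = 64,
                         site_cover_sd = 8, latent_noise_sd = 50,
                         latent_weights = default_latent_weights(),
                         attr_effects = NULL,
                         elo = elo_config(), predictor = predictor_config(),
                         run_respondent_test = TRUE,
                         n_points = 50, seed = 1) {
  stopifnot(n_sites_per_habitat >= 1, photos_per_site >= 1,
            survey_subset_per_habitat >= 1, n_respondents >= 1,
            pairs_each >= 1, qc_fail_prob >= 0, qc_fail_prob < 1,
            image_side >= 16, n_points >= 1)
  if (survey_subset_per_habitat > n_sites_per_habitat * photos_per_site) {
    stop("survey subset per habitat exceeds the photos available per habitat")
  }
  structure(list(
    n_sites_per_habitat = n_sites_per_habitat,
    photos_per_site = photos_per_site,
    survey_subset_per_habitat = survey_subset_per_habitat,
    n_respondents = n_respondents, pairs_each = pairs_each,
    qc_fail_prob = qc_fail_prob, image_side = image_side,
    site_cover_sd = site_cover_sd, latent_noise_sd = latent_noise_sd,
    latent_weights = latent_weights, attr_effects = attr_effects,
    elo = elo, predictor = predictor,
    run_respondent_test = run_respondent_test,
    n_points = n_points, seed = seed), class = "study_config")
}

#' Quality-control filter on the colour-card flag
#'
#' Keeps only photographs whose `qc_pass` flag is set (the flag stands in
#' for the human judgement that the camera's automatic colour adjustment
#' worked) and returns a discard log alongside.
#'
#' @param images List of [quadrat_image()] objects, or a data.frame with
#'   `image_id` and `qc_pass` columns.
#' @return List: `images` (survivors, same type as input) and `discarded`
#'   (data.frame of `image_id`, `reason`).
#' @export
qc_filter <- function(images) {
  if (is.data.frame(images)) {
    pass <- images$qc_pass
    ids <- images$image_id
    kept <- images[pass, , drop = FALSE]
  } else {
    pass <- vapply(images, function(im) isTRUE(im$qc_pass), logical(1))
    ids <- vapply(images, function(im) im$image_id, character(1))
    kept <- images[pass]
  }
  if (!any(pass)) warning("all photographs failed QC; nothing survives")
  list(images = kept,
       discarded = data.frame(image_id = ids[!pass],
                              reason = rep("colour-card QC failure", sum(!pass)),
                              stringsAsFactors = FALSE))
}

#' Run the full synthetic aesthetic-value study
#'
#' End-to-end orchestration at desk scale: generate quadrat photographs for
#' every site with ground truth, apply the QC filter, extract the nine
#' photograph features, draw the survey subset and simulate pairwise
#' choices, exclude colour-deficient respondents, compute bootstrapped Elo
#' ratings, train the image predictor on the 70/15/15 split and predict all
#' surviving photos, screen and regress the features against the predicted
#' ratings with importance shares, compare each retained response across
#' habitats with mixed models and Tukey letters, and (optionally) test the
#' respondent socio-cultural effects. Fully reproducible: every stage draws
#' from a named substream of `config$seed`.
#'
#' @param config A [study_config()].
#' @param keep_images Keep the generated images/masks in the returned object
#'   (default TRUE; set FALSE to save memory).
#' @param verbose Print stage progress.
#' @return An object of class `reef_study`; see [write_study_report()].
#' @export
run_study <- function(config = study_config(), keep_images = TRUE,
                      verbose = interactive()) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  habitats <- c("healthy", "restored", "degraded")
  presets <- default_habitat_presets()

  # --- generation: sites x photos, with site-level cover shifts ------------
  say("generating %d photographs ...",
      3 * config$n_sites_per_habitat * config$photos_per_site)
  images <- list(); masks <- list(); truths <- list()
  meta <- list()
  for (hab in habitats) {
    base <- presets[[hab]]
    site_draws <- with_seed(substream_seed(seed, paste0("sites_", hab)), {
      lapply(seq_len(config$n_sites_per_habitat), function(s) {
        # site-level assemblage: cover shift plus a local subset of the
        # habitat's colour archetypes and growth forms, so sites genuinely
        # differ (the random intercept of the mixed models)
        pal_n <- if (length(base$palette) > 2) {
          sample(max(2L, length(base$palette) - 4L):length(base$palette), 1L)
        } else {
          length(base$palette)
        }
        pool_n <- if (length(base$morphology_pool) > 1) {
          sample(max(1L, ceiling(0.5 * length(base$morphology_pool))):
                   length(base$morphology_pool), 1L)
        } else {
          1L
        }
        list(shift = stats::rnorm(1, 0, config$site_cover_sd),
             palette = base$palette[sample.int(length(base$palette), pal_n)],
             pool = base$morphology_pool[
               sample.int(length(base$morphology_pool), pool_n)])
      })
    })
    for (s in seq_len(config$n_sites_per_habitat)) {
      site_id <- sprintf("%s_s%02d", hab, s)
      preset <- base
      preset$coral_cover_mean <- min(max(preset$coral_cover_mean +
                                           site_draws[[s]]$shift, 0.5), 99)
      preset$palette <- site_draws[[s]]$palette
      preset$morphology_pool <- site_draws[[s]]$pool
      for (ph in seq_len(config$photos_per_site)) {
        image_id <- sprintf("%s_p%02d", site_id, ph)
        g_seed <- substream_seed(seed, paste0("gen_", image_id))
        g <- generate_quadrat(preset, seed = g_seed, side = config$image_side,
                              image_id = image_id, site_id = site_id,
                              qc_pass = TRUE,
                              latent_weights = config$latent_weights,
                              latent_noise_sd = config$latent_noise_sd)
        images[[image_id]] <- g$image
        masks[[image_id]] <- g$mask
        truths[[image_id]] <- g$truth
        meta[[image_id]] <- data.frame(image_id = image_id, site_id = site_id,
                                       habitat = hab, qc_pass = TRUE,
                                       stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, meta)
  n_generated <- nrow(meta)

  # QC failures: the expected count at qc_fail_prob, drawn without
  # replacement (a study of 900 photos at 17/900 discards exactly 17)
  n_fail <- round(config$qc_fail_prob * n_generated)
  fail_ids <- with_seed(substream_seed(seed, "qc"),
                        sample(meta$image_id, n_fail))
  for (id in fail_ids) images[[id]]$qc_pass <- FALSE
  meta$qc_pass[meta$image_id %in% fail_ids] <- FALSE

  # --- QC filter -----------------------------------------------------------
  qc <- qc_filter(images)
  surviving <- names(qc$images)
  say("QC: %d of %d photographs survive", length(surviving), n_generated)

  # --- features ------------------------------------------------------------
  say("extracting features ...")
  features <- do.call(rbind, lapply(surviving, function(id) {
    assemble_features(images[[id]], masks[[id]], n_points = config$n_points,
                      seed = substream_seed(seed, paste0("points_", id)))
  }))

  # --- survey subset and simulated choices ---------------------------------
  subset_ids <- unlist(lapply(habitats, function(hab) {
    pool <- surviving[meta$habitat[match(surviving, meta$image_id)] == hab]
    if (length(pool) < config$survey_subset_per_habitat) {
      stop(sprintf("habitat '%s' has only %d surviving photos; %d needed",
                   hab, length(pool), config$survey_subset_per_habitat))
    }
    with_seed(substream_seed(seed, paste0("subset_", hab)),
              sample(pool, config$survey_subset_per_habitat))
  }))
  latent <- vapply(truths[subset_ids], function(t) t$latent_aesthetic, numeric(1))
  names(latent) <- subset_ids
  say("simulating %d respondents x %d pairs ...",
      config$n_respondents, config$pairs_each)
  records <- simulate_choices(latent, config$n_respondents,
                              pairs_each = config$pairs_each,
                              attr_effects = config$attr_effects,
                              seed = substream_seed(seed, "survey"))
  n_records_raw <- nrow(records)
  records <- exclude_colour_deficient(records)

  # --- Elo ratings ----------------------------------------------------------
  say("computing Elo ratings (%d bootstraps) ...", config$elo$n_bootstrap)
  elo_cfg <- config$elo
  elo_cfg$seed <- substream_seed(seed, "elo")
  ratings <- elo_rate(records, elo_cfg)

  # --- predictor ------------------------------------------------------------
  split <- split_dataset(subset_ids, seed = substream_seed(seed, "split"))
  pred_cfg <- config$predictor
  pred_cfg$seed <- substream_seed(seed, "train")
  say("training predictor (%d epochs) ...", pred_cfg$epochs)
  model <- train_predictor(qc$images, ratings, split$train, split$val, pred_cfg)
  test_pred <- predict_ratings(model, qc$images, split$test)
  rating_lookup <- stats::setNames(ratings$rating_mean, ratings$image_id)
  test_r2 <- evaluate_r2(test_pred, rating_lookup[split$test])
  say("test r-squared: %.3f", test_r2)
  predicted <- predict_ratings(model, qc$images, surviving)

  # --- feature screening, stepwise regression, importance -------------------
  feature_cols <- c("simpson", "pct_black", "pct_blue", "pct_green",
                    "pct_yellow", "pct_grey", "n_colours", "n_morphologies",
                    "pct_live_coral")
  target <- unname(predicted[features$image_id])
  screen <- correlation_filter(features[, feature_cols], target)
  stepwise <- backward_stepwise(features[, screen$retained, drop = FALSE], target)
  importance <- if (length(stepwise$retained) > 0) {
    importance_shares(features[, stepwise$retained, drop = FALSE], target)
  } else {
    NULL
  }

  # --- habitat comparisons ---------------------------------------------------
  say("habitat mixed models ...")
  analysis <- cbind(features, rating = target)
  families <- c(rating = "gaussian", pct_black = "gaussian",
                pct_live_coral = "gaussian", simpson = "gamma_log",
                pct_blue = "gamma_log", n_colours = "poisson",
                n_morphologies = "poisson")
  habitat_tests <- lapply(names(families), function(resp) {
    ht <- fit_habitat_model(analysis, family = families[[resp]],
                            response = resp)
    post <- if (!is.na(ht$p) && ht$p < 0.05) tukey_posthoc(ht) else NULL
    list(test = ht, posthoc = post)
  })
  names(habitat_tests) <- names(families)

  # --- respondent socio-cultural effects -------------------------------------
  resp_effects <- NULL
  if (isTRUE(config$run_respondent_test)) {
    say("respondent-effects GLMM ...")
    resp_effects <- respondent_effects(records)
  }

  structure(list(
    config = config,
    counts = list(n_generated = n_generated,
                  n_discarded = nrow(qc$discarded),
                  n_surviving = length(surviving),
                  n_survey_subset = length(subset_ids),
                  n_records_raw = n_records_raw,
                  n_records_used = nrow(records),
                  split_sizes = lengths(split)),
    meta = meta, discarded = qc$discarded,
    features = features, truths = truths,
    subset_ids = subset_ids, records = records, ratings = ratings,
    split = split, model = model, test_r2 = test_r2,
    predicted = predicted, screen = screen, stepwise = stepwise,
    importance = importance, habitat_tests = habitat_tests,
    respondent_effects = resp_effects,
    images = if (keep_images) qc$images else NULL,
    masks = if (keep_images) masks else NULL),
    class = "reef_study")
}

#' @export
print.reef_study <- function(x, ...) {
  cat("<reef_study>\n")
  cat(sprintf("  photographs: %d generated, %d discarded by QC, %d analysed\n",
              x$counts$n_generated, x$counts$n_discarded, x$counts$n_surviving))
  cat(sprintf("  survey: %d photos, %d choice records used (of %d)\n",
              x$counts$n_survey_subset, x$counts$n_records_used,
              x$counts$n_records_raw))
  cat(sprintf("  split: %d train / %d val / %d test; predictor test r2 = %.3f\n",
              x$counts$split_sizes[1], x$counts$split_sizes[2],
              x$counts$split_sizes[3], x$test_r2))
  cat(sprintf("  stepwise model: %s (R2 = %.3f)\n",
              paste(x$stepwise$retained, collapse = ", "),
              x$stepwise$r_squared))
  if (!is.null(x$importance)) {
    imp <- sort(x$importance, decreasing = TRUE)
    cat("  importance shares:",
        paste(sprintf("%s %.1f%%", names(imp), imp), collapse = ", "), "\n")
  }
  rt <- x$habitat_tests$rating
  if (!is.null(rt)) {
    cat(sprintf("  rating ~ habitat: chi2 = %.2f, df = %d, p = %.3g\n",
                rt$test$chi2, rt$test$df, rt$test$p))
    if (!is.null(rt$posthoc)) {
      cat("  Tukey letters:",
          paste(names(rt$posthoc$letters), rt$posthoc$letters,
                sep = "=", collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Write the study's tables and report to a directory
#'
#' Writes `features.csv`, `ratings.csv`, `predictions.csv`, `choices.csv`,
#' `discarded.csv` and a `report.json` holding every computed statistic
#' (counts, predictor accuracy, screening log, stepwise coefficients,
#' importance shares, habitat tests with letters, respondent effects and the
#' master seed).
#'
#' @param study A `reef_study` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the report path.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "reef_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$features, file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(study$ratings, file.path(dir, "ratings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(image_id = names(study$predicted),
                              predicted_rating = as.numeric(study$predicted)),
                   file.path(dir, "predictions.csv"), row.names = FALSE)
  utils::write.csv(study$records, file.path(dir, "choices.csv"), row.names = FALSE)
  utils::write.csv(study$discarded, file.path(dir, "discarded.csv"), row.names = FALSE)
  report <- list(
    seed = study$config$seed,
    counts = study$counts,
    test_r2 = study$test_r2,
    screening = study$screen$removals,
    stepwise = list(retained = study$stepwise$retained,
                    coefficients = study$stepwise$coefficients,
                    r_squared = study$stepwise$r_squared),
    importance = as.list(study$importance),
    habitat_tests = lapply(study$habitat_tests, function(ht) {
      list(response = ht$test$response, family = ht$test$family,
           chi2 = ht$test$chi2, df = ht$test$df, p = ht$test$p,
           singular = ht$test$singular,
           letters = if (!is.null(ht$posthoc)) as.list(ht$posthoc$letters))
    }),
    respondent_effects = study$respondent_effects
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
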