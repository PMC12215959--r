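#' Configuration for Elo rating with randomized-order bootstrapping
#'
#' The paired-comparison rating used the Elo algorithm with 1,000
#' randomized-order bootstrap runs. The start value and K factor are not
#' published for the original analysis; the defaults here (start 0, K 100)
#' follow the cited rating package's documented defaults and are
#' configurable. Absolute scale does not affect any downstream rank-based or
#' linear analysis.
#'
#' @param start_value Initial rating for every photo.
#' @param k_factor Update step size in rating points (> 0).
#' @param n_bootstrap Number of randomized-order runs (>= 1; survey default
#'   1,000).
#' @param seed Master seed spawning one shuffling substream per run.
#' @return An object of class `elo_config`.
#' @export
elo_config <- function(start_value = 0, k_factor = 100,
                       n_bootstrap = 1000, seed = 1) {
  if (!is.numeric(k_factor) || k_factor <= 0) stop("k_factor must be > 0")
  if (!is.numeric(n_bootstrap) || n_bootstrap < 1) stop("n_bootstrap must be >= 1")
  structure(list(start_value = start_value, k_factor = k_factor,
                 n_bootstrap = as.integer(n_bootstrap), seed = seed),
            class = "elo_config")
}

#' One Elo update after a pairwise contest
#'
#' With expectation `E_w = 1 / (1 + 10^((r_l - r_w) / 400))`, the winner
#' gains `k * (1 - E_w)` points and the loser loses the same amount, so total
#' rating is conserved exactly.
#'
#' @param r_winner,r_loser Current ratings (vectorised).
#' @param k K factor (update step size).
#' @return List with elements `winner` and `loser`: the updated ratings.
#' @export
#' @examples
#' elo_update(0, 0, k = 100) # +50 / -50
elo_update <- function(r_winner, r_loser, k = 100) {
  e_w <- elo_win_prob(r_winner, r_loser)
  d <- k * (1 - e_w)
  list(winner = r_winner + d, loser = r_loser - d)
}

#' Elo aesthetic ratings from preference records
#'
#' Runs `n_bootstrap` independent passes over the records, each in a freshly
#' shuffled order with all photos starting at `start_value`, and reports the
#' per-photo mean and SD of the final ratings across runs. Order
#' randomization is the bootstrap of the paired-comparison literature: a
#' single sequential pass depends on record order, the across-run mean does
#' not. All runs are advanced simultaneously (one matrix update per record
#' step), so the survey-scale default of 1,000 runs takes seconds.
#'
#' @param records Preference records with columns `photo_a`, `photo_b`,
#'   `winner` (e.g. from [simulate_choices()], ideally after
#'   [exclude_colour_deficient()]).
#' @param config An [elo_config()].
#' @return A data.frame of class `elo_ratings`: `image_id`, `rating_mean`,
#'   `rating_sd`, `n_comparisons`.
#' @export
elo_rate <- function(records, config = elo_config()) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no preference records to rate")
  }
  stopifnot(all(c("photo_a", "photo_b", "winner") %in% names(records)))
  if (any(records$winner != records$photo_a &
            records$winner != records$photo_b)) {
    stop("every winner must equal photo_a or photo_b of its record")
  }
  ids <- sort(unique(c(records$photo_a, records$photo_b)))
  n_img <- length(ids)
  n_rec <- nrow(records)
  n_boot <- config$n_bootstrap
  w_idx <- match(records$winner, ids)
  l_idx <- match(ifelse(records$winner == records$photo_a,
                        records$photo_b, records$photo_a), ids)
  orders <- with_seed(substream_seed(config$seed, "elo_orders"), {
    vapply(seq_len(n_boot), function(b) sample.int(n_rec), integer(n_rec))
  })
  orders <- matrix(orders, nrow = n_rec)
  ratings <- matrix(config$start_value, n_img, n_boot)
  cols <- seq_len(n_boot)
  k <- config$k_factor
  for (t in seq_len(n_rec)) {
    rec <- orders[t, ]
    wi <- cbind(w_idx[rec], cols)
    li <- cbind(l_idx[rec], cols)
    rw <- ratings[wi]
    rl <- ratings[li]
    d <- k * (1 - 1 / (1 + 10^((rl - rw) / 400)))
    ratings[wi] <- rw + d
    ratings[li] <- rl - d
  }
  out <- data.frame(
    image_id = ids,
    rating_mean = rowMeans(ratings),
    rating_sd = apply(ratings, 1, stats::sd),
    n_comparisons = tabulate(c(match(records$photo_a, ids),
                               match(records$photo_b, ids)), nbins = n_img)
  )
  if (n_boot == 1L) out$rating_sd <- 0
  class(out) <- c("elo_ratings", "data.frame")
  out
}
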