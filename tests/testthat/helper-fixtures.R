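# Small programmatic fixtures shared across test files.

# A solid-colour image of the given side.
solid_image <- function(rgb, side = 8) {
  arr <- array(0L, dim = c(side, side, 3))
  for (ch in 1:3) arr[, , ch] <- as.integer(rgb[ch])
  arr
}

# Left half one colour, right half another.
half_half_image <- function(rgb_left, rgb_right, side = 8) {
  arr <- solid_image(rgb_left, side)
  for (ch in 1:3) arr[, (side / 2 + 1):side, ch] <- as.integer(rgb_right[ch])
  arr
}

# A mask with the first `n_coral` pixels (column-major) set to a coral label.
toy_mask <- function(side = 10, n_coral = 0, morphology = "massive",
                     image_id = "toy") {
  labels <- matrix(0L, side, side)
  if (n_coral > 0) {
    lab <- 10L + match(morphology, coral_morphologies())
    labels[seq_len(n_coral)] <- lab
  }
  benthic_mask(labels, image_id)
}

# A tiny preference-record table with explicit winners.
toy_records <- function(winners, losers, respondent_id = "r1") {
  data.frame(respondent_id = respondent_id, photo_a = winners,
             photo_b = losers, winner = winners,
             colour_deficiency = FALSE, stringsAsFactors = FALSE)
}

# Deterministic latent-score fixture: n images with evenly spaced scores.
toy_scores <- function(n, spread = 400) {
  stats::setNames(seq(0, spread, length.out = n), sprintf("p%02d", seq_len(n)))
}

# All permutations of 1..n (for brute-force ordering oracles).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}
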