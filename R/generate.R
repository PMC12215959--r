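#' Generate one synthetic quadrat photograph with ground truth
#'
#' Renders a square benthic quadrat image for a habitat preset: coral
#' colonies drawn as parametric shapes per growth form (dendritic strokes for
#' branching, lobed blobs for massive/submassive, discs for tabulate and
#' mushroom, ridged patches for encrusting, arc segments for foliose,
#' parallel fingers for digitate), grey-toned rubble blobs, restoration-frame
#' bars where present, sand elsewhere, and near-black shadow pixels adjacent
#' to colonies in proportion to coral cover (the structural-complexity
#' proxy). Cover targets are drawn from the preset's moment-matched beta
#' distributions and realized *exactly* in the label mask: the returned
#' ground-truth covers equal the pixel fractions of the mask.
#'
#' All randomness (covers, colony count, placement, colours, shapes, shadow,
#' latent-score noise) is fixed by `seed`: identical calls are bit-identical.
#'
#' @param preset A [habitat_preset()].
#' @param seed Integer seed fixing all randomness.
#' @param side Image side length in pixels (desk-scale default 64).
#' @param image_id,site_id,depth_m,qc_pass Metadata for the image.
#' @param latent_weights,latent_noise_sd Passed to [latent_score()] to fill
#'   the ground truth's latent aesthetic score.
#' @return List with elements `image` ([quadrat_image()]), `mask`
#'   ([benthic_mask()]) and `truth` (class `ground_truth`: `image_id`,
#'   `true_cover` percent per class summing to 100, `true_morphologies`,
#'   `true_colour_shares` percent per colour group, `latent_aesthetic`).
#' @export
generate_quadrat <- function(preset, seed, side = 64,
                             image_id = paste0("q", seed),
                             site_id = NA_character_, depth_m = 3,
                             qc_pass = TRUE,
                             latent_weights = default_latent_weights(),
                             latent_noise_sd = 50) {
  validate_preset(preset)
  stopifnot(side >= 16)
  with_seed(seed, {
    npx <- side * side
    cov <- sample_covers(preset)
    n_coral <- min(round(cov$coral / 100 * npx), npx)
    n_rubble <- round(cov$rubble / 100 * npx)
    n_frame <- round(cov$frame / 100 * npx)

    labels <- matrix(0L, side, side) # 0 = sand
    colony <- matrix(0L, side, side)
    colony_colour <- list()
    morphs <- coral_morphologies()

    # Per-quadrat community draw: each quadrat hosts a subset of the
    # preset's colour archetypes and growth forms, and the archetypes carry
    # Dirichlet-distributed abundance weights (a small concentration gives a
    # single dominant colour, a large one an even mix). Colour richness,
    # colour evenness and morphology richness therefore all vary
    # independently of coral cover, as in real assemblages where a dense
    # stand can be monospecific.
    pal <- preset$palette
    if (length(pal) > 2L) {
      pal <- pal[sample.int(length(pal),
                            sample(2L:length(pal), 1L))]
    }
    alpha <- stats::runif(1, 0.3, 3)
    pal_w <- stats::rgamma(length(pal), shape = alpha)
    pal_w <- pal_w / sum(pal_w)
    pool <- preset$morphology_pool
    if (length(pool) > 1L) {
      lo <- max(1L, ceiling(length(pool) / 2))
      pool <- pool[sample.int(length(pool), sample(lo:length(pool), 1L))]
    }

    # --- coral colonies (exact pixel count via last-colony trim) ---
    painted <- 0L; cid <- 0L; tries <- 0L
    while (painted < n_coral && tries < 500L) {
      tries <- tries + 1L
      m <- if (length(pool) == 1L) pool else sample(pool, 1L)
      # log-uniform colony radius: occasional large colonies dominate a
      # quadrat, driving evenness variation at fixed richness
      r0 <- side * exp(stats::runif(1, log(0.04), log(0.30)))
      cx <- stats::runif(1, 1, side); cy <- stats::runif(1, 1, side)
      stamp <- stamp_morphology(m, side, cx, cy, r0)
      new <- which(stamp & labels < 10L)
      if (length(new) == 0L) next
      excess <- painted + length(new) - n_coral
      if (excess > 0L) new <- sample_int(new, length(new) - excess)
      cid <- cid + 1L
      labels[new] <- 10L + match(m, morphs)
      colony[new] <- cid
      colony_colour[[cid]] <- jitter_colour(pick_palette(pal, pal_w))
      painted <- painted + length(new)
    }
    if (painted < n_coral) { # degenerate geometry: fill with scattered pixels
      free <- which(labels == 0L)
      add <- sample_int(free, min(n_coral - painted, length(free)))
      cid <- cid + 1L
      m <- pool[1L]
      labels[add] <- 10L + match(m, morphs)
      colony[add] <- cid
      colony_colour[[cid]] <- jitter_colour(pick_palette(pal, pal_w))
    }

    # --- rubble blobs on free pixels ---
    labels <- paint_exact(labels, 1L, n_rubble, function() {
      r0 <- side * stats::runif(1, 0.03, 0.10)
      cx <- stats::runif(1, 1, side); cy <- stats::runif(1, 1, side)
      stamp_blob(side, cx, cy, r0)
    })

    # --- restoration frame bars ---
    if (n_frame > 0L) {
      labels <- paint_exact(labels, 3L, n_frame, function() {
        stamp_bar(side, stats::runif(1, 1, side), stats::runif(1, 1, side),
                  ang = stats::runif(1, 0, pi), len = side * 0.8,
                  thick = max(1L, round(side / 32)))
      })
    }

    # --- shadow pixels (image-level only; mask keeps the class beneath) ---
    coral_mask <- labels >= 10L
    shadow_frac <- preset$shadow_scale * (sum(coral_mask) / npx) *
      stats::runif(1, 0.3, 1)
    n_shadow <- round(shadow_frac * npx)
    shadow_idx <- integer(0)
    if (n_shadow > 0L) {
      cand <- which(dilate8(coral_mask) & !coral_mask)
      if (length(cand) < n_shadow) {
        extra <- setdiff(which(!coral_mask), cand)
        cand <- c(cand, sample_int(extra, min(n_shadow - length(cand), length(extra))))
      }
      shadow_idx <- sample_int(cand, min(n_shadow, length(cand)))
    }

    pixels <- render_quadrat(labels, colony, colony_colour, shadow_idx, side)

    img <- quadrat_image(pixels, image_id, site_id = site_id,
                         habitat = preset$name, depth_m = depth_m,
                         qc_pass = qc_pass)
    mask <- benthic_mask(labels, image_id)
    truth <- structure(
      list(image_id = image_id,
           true_cover = exact_cover(mask),
           true_morphologies = sort(unique(stats::na.omit(
             mask_morphology_vector(mask)))),
           true_colour_shares = pixel_group_shares(pixels),
           true_colour_diversity = simpson_diversity(
             tabulate(pixel_bin_index(pixels), nbins = 64L) / npx),
           latent_aesthetic = NA_real_),
      class = "ground_truth"
    )
    truth$latent_aesthetic <- latent_score(truth, latent_weights,
                                           noise_sd = latent_noise_sd,
                                           seed = NULL)
    list(image = img, mask = mask, truth = truth)
  })
}

# sample() without the length-1 surprise.
sample_int <- function(x, n) x[sample.int(length(x), n)]

pick_palette <- function(palette, weights = NULL) {
  palette[[sample.int(length(palette), 1L, prob = weights)]]
}

jitter_colour <- function(rgb) {
  as.integer(pmax(0, pmin(255, rgb + round(stats::runif(3, -15, 15)))))
}

# Draw coral and rubble cover from moment-matched beta distributions; if the
# joint draw (plus any frame share) exceeds 100%, trim the excess from the
# minor benthic class first so the habitat's dominant class keeps its stated
# distribution. Remainder of the quadrat is sand.
sample_covers <- function(preset) {
  coral <- rbeta_cover(preset$coral_cover_mean, preset$coral_cover_sd)
  rubble <- rbeta_cover(preset$rubble_cover_mean, preset$rubble_cover_sd)
  frame <- if (isTRUE(preset$frame_present)) preset$frame_cover_pct else 0
  excess <- coral + rubble + frame - 100
  if (excess > 0) {
    if (coral <= rubble) {
      cut <- min(coral, excess); coral <- coral - cut; excess <- excess - cut
      cut <- min(rubble, excess); rubble <- rubble - cut; excess <- excess - cut
    } else {
      cut <- min(rubble, excess); rubble <- rubble - cut; excess <- excess - cut
      cut <- min(coral, excess); coral <- coral - cut; excess <- excess - cut
    }
    frame <- frame - excess
  }
  list(coral = coral, rubble = rubble, frame = frame)
}

# One beta draw on [0, 100] with mean m and SD s (percent). SD 0 (or a
# degenerate mean) returns the mean itself; an infeasible SD is shrunk to
# the largest variance a [0,1] distribution with that mean supports.
rbeta_cover <- function(m, s) {
  if (s <= 0 || m <= 0 || m >= 100) return(min(max(m, 0), 100))
  mu <- m / 100; v <- (s / 100)^2
  vmax <- mu * (1 - mu)
  if (v >= vmax) v <- 0.99 * vmax
  nu <- mu * (1 - mu) / v - 1
  100 * stats::rbeta(1, mu * nu, (1 - mu) * nu)
}

# Paint blobs of `label` onto free (sand) pixels until exactly `target`
# pixels carry it; the last blob is trimmed at random to hit the count, and
# a scattered fill tops up if the stamp generator stalls.
paint_exact <- function(labels, label, target, stamp_fun, max_tries = 500L) {
  if (target <= 0L) return(labels)
  free_n <- sum(labels == 0L)
  target <- min(target, free_n)
  painted <- 0L; tries <- 0L
  while (painted < target && tries < max_tries) {
    tries <- tries + 1L
    new <- which(stamp_fun() & labels == 0L)
    if (length(new) == 0L) next
    excess <- painted + length(new) - target
    if (excess > 0L) new <- sample_int(new, length(new) - excess)
    labels[new] <- label
    painted <- painted + length(new)
  }
  if (painted < target) {
    free <- which(labels == 0L)
    labels[sample_int(free, target - painted)] <- label
  }
  labels
}

coord_grids <- function(side) {
  Y <- matrix(seq_len(side), side, side) # row index
  list(X = t(Y), Y = Y)
}

# Parametric colony stamps, one per growth form. Only the resulting label
# mask feeds the analysis, so rendering fidelity is deliberately coarse.
stamp_morphology <- function(m, side, cx, cy, r0) {
  g <- coord_grids(side)
  dx <- g$X - cx; dy <- g$Y - cy
  r <- sqrt(dx^2 + dy^2); th <- atan2(dy, dx)
  switch(m,
    massive = {
      phi <- stats::runif(1, 0, 2 * pi)
      r <= r0 * (1 + 0.25 * sin(3 * th + phi))
    },
    submassive = {
      phi <- stats::runif(1, 0, 2 * pi)
      r <= 0.8 * r0 * (1 + 0.35 * sin(5 * th + phi))
    },
    tabulate = r <= 1.3 * r0,
    mushroom = r <= 0.5 * r0,
    encrusting = {
      out <- matrix(FALSE, side, side)
      for (i in 1:6) {
        ox <- cx + stats::rnorm(1, 0, 0.7 * r0)
        oy <- cy + stats::rnorm(1, 0, 0.7 * r0)
        rr <- r0 * stats::runif(1, 0.3, 0.6)
        out <- out | ((g$X - ox)^2 + (g$Y - oy)^2 <= rr^2)
      }
      out
    },
    foliose = {
      a0 <- stats::runif(1, -pi, pi)
      width <- stats::runif(1, pi, 2 * pi)
      dth <- (th - a0) %% (2 * pi)
      r >= 0.55 * r0 & r <= 1.1 * r0 & dth <= width
    },
    branching = {
      nb <- sample(4:8, 1)
      pts <- matrix(numeric(0), ncol = 2)
      for (b in seq_len(nb)) {
        ang <- stats::runif(1, 0, 2 * pi)
        x <- cx; y <- cy
        for (s in seq_len(max(3L, round(2.5 * r0)))) {
          ang <- ang + stats::rnorm(1, 0, 0.35)
          x <- x + cos(ang); y <- y + sin(ang)
          pts <- rbind(pts, c(x, y))
        }
      }
      points_stamp(side, pts, thick = max(1L, round(side / 45)))
    },
    digitate = {
      nf <- sample(4:7, 1)
      a0 <- stats::runif(1, 0, pi)
      ux <- cos(a0); uy <- sin(a0) # finger direction
      px <- -uy; py <- ux          # perpendicular spacing
      pts <- matrix(numeric(0), ncol = 2)
      for (k in seq_len(nf)) {
        off <- (k - (nf + 1) / 2) * r0 / 2.2
        bx <- cx + off * px; by <- cy + off * py
        for (s in seq(0, r0 * 0.9, by = 0.7)) {
          pts <- rbind(pts, c(bx + s * ux, by + s * uy))
        }
      }
      points_stamp(side, pts, thick = max(1L, round(r0 / 4)))
    },
    stop("unknown morphology: ", m)
  )
}

stamp_blob <- function(side, cx, cy, r0) {
  g <- coord_grids(side)
  dx <- g$X - cx; dy <- g$Y - cy
  th <- atan2(dy, dx)
  phi <- stats::runif(1, 0, 2 * pi)
  sqrt(dx^2 + dy^2) <= r0 * (1 + 0.4 * sin(4 * th + phi))
}

stamp_bar <- function(side, cx, cy, ang, len, thick) {
  pts <- cbind(cx + seq(-len / 2, len / 2, by = 0.7) * cos(ang),
               cy + seq(-len / 2, len / 2, by = 0.7) * sin(ang))
  points_stamp(side, pts, thick)
}

# Mark all pixels within Chebyshev distance `thick` of any point.
points_stamp <- function(side, pts, thick = 1L) {
  out <- matrix(FALSE, side, side)
  if (nrow(pts) == 0L) return(out)
  xi <- round(pts[, 1]); yi <- round(pts[, 2])
  for (dxo in -thick:thick) {
    for (dyo in -thick:thick) {
      x <- xi + dxo; y <- yi + dyo
      ok <- x >= 1 & x <= side & y >= 1 & y <= side
      out[cbind(y[ok], x[ok])] <- TRUE
    }
  }
  out
}

# 8-neighbour binary dilation.
dilate8 <- function(m) {
  side <- nrow(m)
  out <- m
  shift <- function(mat, dr, dc) {
    res <- matrix(FALSE, side, side)
    rs <- max(1, 1 + dr):min(side, side + dr)
    cs <- max(1, 1 + dc):min(side, side + dc)
    res[rs, cs] <- mat[rs - dr, cs - dc]
    res
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift(m, dr, dc)
  }
  out
}

base_class_colours <- function() {
  list(sand = c(180, 175, 165), rubble = c(135, 135, 135),
       rock = c(100, 100, 100), frame = c(75, 75, 80),
       dead_coral = c(150, 150, 140), soft_coral = c(190, 150, 170),
       sponge = c(170, 120, 60), CCA = c(185, 120, 130),
       gorgonian = c(160, 90, 140))
}

render_quadrat <- function(labels, colony, colony_colour, shadow_idx, side) {
  npx <- side * side
  legend <- default_mask_legend()
  cls <- legend$class[match(as.vector(labels), legend$label)]
  base <- base_class_colours()
  px <- matrix(0, npx, 3)
  for (k in names(base)) {
    sel <- cls == k
    if (any(sel)) px[sel, ] <- matrix(base[[k]], sum(sel), 3, byrow = TRUE)
  }
  cid <- as.vector(colony)
  coral_sel <- cid > 0L
  if (any(coral_sel)) {
    cols <- t(vapply(colony_colour, as.numeric, numeric(3)))
    px[coral_sel, ] <- cols[cid[coral_sel], , drop = FALSE]
  }
  noise_sd <- ifelse(cls == "rubble", 12, 8)
  px <- px + matrix(stats::rnorm(npx * 3), npx, 3) * noise_sd
  if (length(shadow_idx)) {
    px[shadow_idx, ] <- matrix(stats::runif(length(shadow_idx) * 3, 0, 15),
                               length(shadow_idx), 3)
  }
  arr <- array(as.integer(pmax(0, pmin(255, round(px)))), dim = c(side, side, 3))
  arr
}
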