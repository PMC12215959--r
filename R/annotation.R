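#' Point-intercept benthic cover estimate from an annotation mask
#'
#' Implements the survey's cover protocol: `n_points` points are placed
#' uniformly at random over the photograph (without replacement, at pixel
#' centres) and the benthic class beneath each point is recorded. Per-class
#' percent cover is `hits / n_points * 100` — with the default 50 points this
#' is the survey's "double the point count" rule. The sampling seed is
#' recorded in the output for reproducibility.
#'
#' @param mask A [benthic_mask()].
#' @param n_points Number of points (default 50).
#' @param seed Optional integer seed for point placement.
#' @return Named numeric percent per benthic class (all legend classes,
#'   zeros included), summing to 100, with attributes `n_points` and `seed`.
#' @seealso [exact_cover()] for the exhaustive pixel-count oracle.
#' @export
point_count_cover <- function(mask, n_points = 50, seed = NULL) {
  stopifnot(inherits(mask, "benthic_mask"), n_points >= 1)
  npx <- length(mask$labels)
  if (n_points > npx) {
    stop(sprintf("n_points (%d) exceeds the pixel count (%d)", n_points, npx))
  }
  idx <- with_seed(seed, sample.int(npx, n_points))
  cls <- mask_class_vector(mask)[idx]
  all_classes <- unique(mask$legend$class)
  hits <- vapply(all_classes, function(k) sum(cls == k), numeric(1))
  out <- 100 * hits / n_points
  attr(out, "n_points") <- as.integer(n_points)
  attr(out, "seed") <- seed
  out
}

#' Number of coral growth forms present in a mask
#'
#' Counts the distinct coral morphologies (of the eight recognised growth
#' forms) with at least one hard-coral pixel; the shape-diversity feature.
#'
#' @param mask A [benthic_mask()].
#' @return Integer in 0-8.
#' @export
morphology_richness <- function(mask) {
  stopifnot(inherits(mask, "benthic_mask"))
  length(unique(stats::na.omit(mask_morphology_vector(mask))))
}

#' Assemble the nine photograph features for one image
#'
#' Produces the per-photo feature row entering the aesthetic-rating
#' regression: Gini-Simpson colour diversity, the five colour-group percents
#' (black doubling as the shadow / structural-complexity proxy), colour
#' richness, growth-form richness, and point-intercept live hard-coral
#' cover.
#'
#' @param img A [quadrat_image()].
#' @param mask The paired [benthic_mask()] (same `image_id`).
#' @param tp Optional precomputed [colour_thumbprint()] of `img`.
#' @param groups Optional precomputed [group_shares()].
#' @param mapping Bin-to-group table (default [default_bin_groups()]).
#' @param n_points,seed Point-intercept settings for live-coral cover.
#' @param simpson_on Compute the Simpson index on the 64 thumbprint bins
#'   (default, the stated unit of the colour analysis) or on the colour
#'   groups.
#' @return One-row data.frame: `image_id`, `site_id`, `habitat`, `simpson`,
#'   `pct_black`, `pct_blue`, `pct_green`, `pct_yellow`, `pct_grey`,
#'   `n_colours`, `n_morphologies`, `pct_live_coral`.
#' @export
assemble_features <- function(img, mask, tp = NULL, groups = NULL,
                              mapping = default_bin_groups(),
                              n_points = 50, seed = NULL,
                              simpson_on = c("bins", "groups")) {
  stopifnot(inherits(img, "quadrat_image"), inherits(mask, "benthic_mask"))
  if (img$image_id != mask$image_id) {
    stop(sprintf("image_id mismatch: image '%s' vs mask '%s'",
                 img$image_id, mask$image_id))
  }
  simpson_on <- match.arg(simpson_on)
  if (is.null(tp)) tp <- colour_thumbprint(img)
  if (is.null(groups)) groups <- group_shares(tp, mapping)
  cover <- point_count_cover(mask, n_points = n_points, seed = seed)
  simpson <- if (simpson_on == "bins") {
    simpson_diversity(tp)
  } else {
    simpson_diversity(groups / 100)
  }
  data.frame(
    image_id = img$image_id, site_id = img$site_id, habitat = img$habitat,
    simpson = simpson,
    pct_black = unname(groups["black"]), pct_blue = unname(groups["blue"]),
    pct_green = unname(groups["green"]), pct_yellow = unname(groups["yellow"]),
    pct_grey = unname(groups["grey"]),
    n_colours = count_colours(tp),
    n_morphologies = morphology_richness(mask),
    pct_live_coral = unname(cover["hard_coral"]),
    stringsAsFactors = FALSE
  )
}

#' Long-format cover table for a set of masks
#'
#' @param masks List of [benthic_mask()] objects.
#' @param n_points,seed Point-intercept settings; each mask gets its own
#'   substream of `seed`.
#' @return data.frame with columns `image_id`, `class`, `percent`,
#'   `n_points`, `seed`.
#' @export
cover_table <- function(masks, n_points = 50, seed = 1) {
  rows <- lapply(masks, function(m) {
    s <- substream_seed(seed, paste0("cover_", m$image_id))
    cov <- point_count_cover(m, n_points = n_points, seed = s)
    data.frame(image_id = m$image_id, class = names(cov),
               percent = as.numeric(cov), n_points = n_points, seed = s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
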