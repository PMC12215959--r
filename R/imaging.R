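#' Standardize a photograph to a square of fixed side length
#'
#' Reproduces the survey's photo standardization: every quadrat photograph is
#' reduced to the same pixel count. Non-square inputs are centre-cropped to a
#' square first; the square is then resampled to `target_side` pixels per
#' side by deterministic nearest-neighbour index mapping (an already
#' `target_side`-sized input passes through unchanged).
#'
#' @param x A [quadrat_image()] or an `H x W x 3` pixel array (0-255).
#' @param target_side Output side length in pixels (default 700, the survey
#'   standard; the desk-scale predictor uses 64).
#' @return Same type as the input, with `target_side x target_side` pixels.
#' @export
standardize_image <- function(x, target_side = 700) {
  if (inherits(x, "quadrat_image")) {
    x$pixels <- standardize_image(x$pixels, target_side)
    return(x)
  }
  if (length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop("input must have 3 colour channels (H x W x 3)")
  }
  h <- dim(x)[1]; w <- dim(x)[2]
  s <- min(h, w)
  r0 <- floor((h - s) / 2); c0 <- floor((w - s) / 2)
  sq <- x[(r0 + 1):(r0 + s), (c0 + 1):(c0 + s), , drop = FALSE]
  if (s == target_side) {
    storage.mode(sq) <- "integer"
    return(sq)
  }
  src <- pmin(pmax(floor((seq_len(target_side) - 0.5) * s / target_side) + 1L, 1L), s)
  out <- sq[src, src, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

# 4 equal divisions per channel: [0,64), [64,128), [128,192), [192,256).
channel_division <- function(v) pmin(as.integer(v) %/% 64L, 3L)

# Per-pixel bin index 1..64, red-major: 16*r_div + 4*g_div + b_div + 1.
pixel_bin_index <- function(pixels) {
  r <- channel_division(pixels[, , 1])
  g <- channel_division(pixels[, , 2])
  b <- channel_division(pixels[, , 3])
  as.vector(16L * r + 4L * g + b + 1L)
}

#' Compute the 64-bin RGB colour thumbprint of an image
#'
#' Each pixel is assigned to exactly one of the 4 x 4 x 4 = 64 half-open
#' boxes of RGB colourspace (channel divisions \[0,64), \[64,128),
#' \[128,192), \[192,256), red-major bin order); the thumbprint is the vector
#' of bin proportions, which sums to 1.
#'
#' @param x A [quadrat_image()] or an `H x W x 3` pixel array.
#' @return An object of class `color_thumbprint` with fields `proportions`
#'   (length-64 numeric) and `bin_edges`.
#' @export
colour_thumbprint <- function(x) {
  pixels <- if (inherits(x, "quadrat_image")) x$pixels else x
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("input must have 3 colour channels (H x W x 3)")
  }
  n <- prod(dim(pixels)[1:2])
  if (n == 0) stop("empty image")
  counts <- tabulate(pixel_bin_index(pixels), nbins = 64L)
  structure(list(proportions = counts / n,
                 bin_edges = c(0L, 64L, 128L, 192L, 256L)),
            class = "color_thumbprint")
}

#' @export
print.color_thumbprint <- function(x, ...) {
  nz <- sum(x$proportions > 0)
  cat(sprintf("<color_thumbprint> 64 bins, %d occupied, top bin %.1f%%\n",
              nz, 100 * max(x$proportions)))
  invisible(x)
}

#' Default mapping of the 64 colour bins to named colour groups
#'
#' Assigns every bin to exactly one of black, blue, green, yellow, grey or
#' other, from the bin's channel divisions (r, g, b in 0-3):
#' black = all channels in the lowest division; grey = equal divisions above
#' the lowest; blue = blue-dominant; green = green-dominant; yellow = red and
#' green equal and above blue; everything else (browns, purples, teals) =
#' other. The published bin-to-group table can be substituted via
#' [read_bin_groups()]; an editable copy of this default ships at
#' `system.file("extdata", "colour_bin_groups.csv", package = "reefbeauty")`.
#'
#' @return A data.frame with columns `bin_index`, `r_div`, `g_div`, `b_div`,
#'   `group`.
#' @export
default_bin_groups <- function() {
  divs <- expand.grid(b_div = 0:3, g_div = 0:3, r_div = 0:3)[, 3:1]
  r <- divs$r_div; g <- divs$g_div; b <- divs$b_div
  group <- rep("other", 64L)
  group[g > r & g > b] <- "green"
  group[b > r & b > g] <- "blue"
  group[r == g & b < r] <- "yellow"
  group[r == g & g == b & r > 0] <- "grey"
  group[r == 0 & g == 0 & b == 0] <- "black"
  data.frame(bin_index = seq_len(64L), divs, group, stringsAsFactors = FALSE)
}

#' Read / write a bin-to-group mapping table
#'
#' @param path CSV file with columns `bin_index`, `r_div`, `g_div`, `b_div`,
#'   `group`.
#' @return `read_bin_groups` returns the mapping data.frame.
#' @export
read_bin_groups <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_bin_groups(m)
  m
}

#' @rdname read_bin_groups
#' @param mapping Mapping data.frame as from [default_bin_groups()].
#' @export
write_bin_groups <- function(mapping, path) {
  validate_bin_groups(mapping)
  utils::write.csv(mapping, path, row.names = FALSE)
  invisible(path)
}

colour_group_names <- function() c("black", "blue", "green", "yellow", "grey", "other")

validate_bin_groups <- function(mapping) {
  if (!all(c("bin_index", "group") %in% names(mapping))) {
    stop("mapping must have columns 'bin_index' and 'group'")
  }
  tab <- table(factor(mapping$bin_index, levels = 1:64))
  missing <- which(tab == 0)
  dup <- which(tab > 1)
  if (length(missing) || length(dup)) {
    stop("bin-to-group mapping must assign each of the 64 bins exactly once; ",
         if (length(missing)) paste0("missing bins: ", paste(missing, collapse = ","), "; "),
         if (length(dup)) paste0("double-assigned bins: ", paste(dup, collapse = ",")))
  }
  bad <- setdiff(unique(mapping$group), colour_group_names())
  if (length(bad)) stop("unknown colour groups in mapping: ", paste(bad, collapse = ", "))
  invisible(mapping)
}

#' Combine thumbprint bins into colour-group percentages
#'
#' @param tp A `color_thumbprint` (or length-64 proportion vector).
#' @param mapping Bin-to-group table; defaults to [default_bin_groups()].
#' @return Named numeric: percent of pixels in black, blue, green, yellow,
#'   grey and other; sums to 100.
#' @export
group_shares <- function(tp, mapping = default_bin_groups()) {
  p <- if (inherits(tp, "color_thumbprint")) tp$proportions else tp
  if (length(p) != 64L) stop("thumbprint must have exactly 64 bins")
  validate_bin_groups(mapping)
  grp <- mapping$group[order(mapping$bin_index)]
  out <- vapply(colour_group_names(),
                function(g) 100 * sum(p[grp == g]), numeric(1))
  out
}

# Direct per-pixel group shares (used by the generator for ground truth and
# as a brute-force oracle in tests).
pixel_group_shares <- function(pixels, mapping = default_bin_groups()) {
  bins <- pixel_bin_index(pixels)
  grp <- mapping$group[order(mapping$bin_index)][bins]
  vapply(colour_group_names(),
         function(g) 100 * sum(grp == g) / length(grp), numeric(1))
}

#' Gini-Simpson diversity of a proportion vector
#'
#' Returns `1 - sum(p^2)`: the probability that two randomly drawn pixels
#' fall in different colour bins. 0 for a monochrome image; maximal
#' (`1 - 1/k`) for a uniform distribution over `k` bins. Computed on the
#' 64-bin thumbprint by default in this pipeline; pass group shares / 100 to
#' compute the group-level variant instead.
#'
#' @param p A `color_thumbprint` or a non-negative vector summing to 1.
#' @param tol Tolerance on the sum-to-1 check.
#' @return Numeric in `[0, 1)`.
#' @export
simpson_diversity <- function(p, tol = 1e-6) {
  if (inherits(p, "color_thumbprint")) p <- p$proportions
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("proportions must sum to 1 (got %.8f)", sum(p)))
  }
  1 - sum(p^2)
}

#' Count colour bins exceeding a proportion threshold
#'
#' The colour-richness feature: the number of thumbprint bins holding
#' strictly more than `threshold` of the image's pixels (default 1%).
#'
#' @param tp A `color_thumbprint` (or length-64 proportion vector).
#' @param threshold Strict lower proportion bound (default 0.01).
#' @return Integer count of qualifying bins.
#' @export
count_colours <- function(tp, threshold = 0.01) {
  p <- if (inherits(tp, "color_thumbprint")) tp$proportions else tp
  if (length(p) != 64L) stop("thumbprint must have exactly 64 bins")
  sum(p > threshold)
}
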