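#' The eight coral growth-form (morphology) classes
#'
#' Growth forms are used as a proxy for coral diversity: branching, digitate,
#' encrusting, foliose, massive, submassive, mushroom and tabulate.
#'
#' @return Character vector of the eight morphology names.
#' @export
coral_morphologies <- function() {
  c("branching", "digitate", "encrusting", "foliose",
    "massive", "submassive", "mushroom", "tabulate")
}

#' Benthic cover classes recognised in masks and cover tables
#'
#' Living biota (hard coral, soft coral, sponge, crustose coralline algae,
#' gorgonian), abiotic components (dead coral, rubble, sand, rock) and
#' restoration frames.
#'
#' @return Character vector of class names.
#' @export
benthic_classes <- function() {
  c("hard_coral", "soft_coral", "sponge", "CCA", "gorgonian",
    "dead_coral", "rubble", "sand", "rock", "frame")
}

#' Default integer label legend for benthic masks
#'
#' Labels 0-9 encode non-coral classes; labels 11-18 encode hard coral, one
#' per morphology (alphabetical). The legend travels with every mask and is
#' serialised as a JSON sidecar next to mask PNGs.
#'
#' @return A data.frame with columns `label`, `class`, `morphology`.
#' @export
default_mask_legend <- function() {
  morphs <- coral_morphologies()
  data.frame(
    label = c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 10L + seq_along(morphs)),
    class = c("sand", "rubble", "rock", "frame", "dead_coral",
              "soft_coral", "sponge", "CCA", "gorgonian",
              rep("hard_coral", length(morphs))),
    morphology = c(rep(NA_character_, 9L), morphs),
    stringsAsFactors = FALSE
  )
}

#' Construct a standardized quadrat photograph object
#'
#' @param pixels Integer array `H x W x 3`, channel values 0-255.
#' @param image_id Unique image identifier.
#' @param site_id Site identifier (used as the mixed-model random effect).
#' @param habitat One of `"healthy"`, `"restored"`, `"degraded"`.
#' @param depth_m Water depth in metres.
#' @param qc_pass Logical: did the photograph pass the colour-card quality
#'   control check (represented here as a metadata flag).
#' @return An object of class `quadrat_image`.
#' @export
quadrat_image <- function(pixels, image_id, site_id = NA_character_,
                          habitat = NA_character_, depth_m = NA_real_,
                          qc_pass = TRUE) {
  pixels <- validate_pixels(pixels)
  if (!is.na(habitat) && !habitat %in% c("healthy", "restored", "degraded")) {
    stop("habitat must be one of 'healthy', 'restored', 'degraded'")
  }
  structure(
    list(image_id = as.character(image_id), pixels = pixels,
         site_id = as.character(site_id), habitat = habitat,
         depth_m = depth_m, qc_pass = isTRUE(qc_pass)),
    class = "quadrat_image"
  )
}

validate_pixels <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("pixels must be an H x W x 3 array (3 colour channels)")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must be within [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  pixels
}

#' Construct a benthic annotation mask aligned to a quadrat image
#'
#' @param labels Integer `H x W` matrix of per-pixel class labels.
#' @param image_id Identifier of the paired image.
#' @param legend Label legend, as from [default_mask_legend()].
#' @return An object of class `benthic_mask`.
#' @export
benthic_mask <- function(labels, image_id, legend = default_mask_legend()) {
  if (!is.matrix(labels)) stop("labels must be an H x W integer matrix")
  storage.mode(labels) <- "integer"
  unknown <- setdiff(unique(as.vector(labels)), legend$label)
  if (length(unknown) > 0) {
    stop("mask contains labels absent from the legend: ",
         paste(unknown, collapse = ", "))
  }
  structure(
    list(image_id = as.character(image_id), labels = labels, legend = legend),
    class = "benthic_mask"
  )
}

#' @export
print.quadrat_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<quadrat_image> %s  %dx%d px  site=%s habitat=%s qc_pass=%s\n",
              x$image_id, d[1], d[2], x$site_id, x$habitat, x$qc_pass))
  invisible(x)
}

#' @export
print.benthic_mask <- function(x, ...) {
  d <- dim(x$labels)
  cls <- mask_class_vector(x)
  tab <- sort(table(cls), decreasing = TRUE)
  cat(sprintf("<benthic_mask> %s  %dx%d px\n", x$image_id, d[1], d[2]))
  cat("  cover:", paste(sprintf("%s %.1f%%", names(tab), 100 * tab / length(cls)),
                        collapse = ", "), "\n")
  invisible(x)
}

# Per-pixel benthic class (character vector, length H*W) for a mask.
mask_class_vector <- function(mask) {
  idx <- match(as.vector(mask$labels), mask$legend$label)
  mask$legend$class[idx]
}

# Per-pixel morphology (NA for non-coral pixels).
mask_morphology_vector <- function(mask) {
  idx <- match(as.vector(mask$labels), mask$legend$label)
  mask$legend$morphology[idx]
}

#' Exact per-class cover of a mask by pixel counting
#'
#' The reference (oracle) cover measure: the exact fraction of mask pixels in
#' each benthic class, in percent. Ground-truth covers produced by
#' [generate_quadrat()] equal this by construction; [point_count_cover()]
#' estimates it from 50 random points.
#'
#' @param mask A [benthic_mask()].
#' @return Named numeric vector of percents over all legend classes,
#'   summing to 100.
#' @export
exact_cover <- function(mask) {
  cls <- mask_class_vector(mask)
  all_classes <- unique(mask$legend$class)
  counts <- vapply(all_classes, function(k) sum(cls == k), numeric(1))
  100 * counts / length(cls)
}
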