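#' Write / read a quadrat image as an 8-bit RGB PNG
#'
#' @param img A [quadrat_image()].
#' @param path Output PNG path.
#' @return `write_quadrat_png` invisibly returns `path`; `read_quadrat_png`
#'   returns a [quadrat_image()] (metadata supplied by the caller).
#' @export
write_quadrat_png <- function(img, path) {
  stopifnot(inherits(img, "quadrat_image"))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}

#' @rdname write_quadrat_png
#' @param image_id,site_id,habitat,depth_m,qc_pass Metadata attached to the
#'   image read back.
#' @export
read_quadrat_png <- function(path, image_id = basename(path),
                             site_id = NA_character_,
                             habitat = NA_character_,
                             depth_m = NA_real_, qc_pass = TRUE) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) stop("expected an RGB PNG, got greyscale")
  if (dim(a)[3] == 4L) a <- a[, , 1:3] # drop alpha
  quadrat_image(array(as.integer(round(a * 255)), dim = dim(a)[1:3]),
                image_id = image_id, site_id = site_id, habitat = habitat,
                depth_m = depth_m, qc_pass = qc_pass)
}

#' Write / read a benthic mask as a label PNG plus a JSON legend sidecar
#'
#' The mask is a single-channel 8-bit PNG holding the integer labels; the
#' legend mapping labels to class/morphology names is written next to it as
#' `<path>.legend.json`.
#'
#' @param mask A [benthic_mask()].
#' @param path Output PNG path.
#' @return `write_mask_png` invisibly returns `path`; `read_mask_png`
#'   returns a [benthic_mask()].
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "benthic_mask"))
  if (max(mask$labels) > 255L) stop("labels exceed 8-bit range")
  png::writePNG(mask$labels / 255, target = path)
  legend_path <- paste0(path, ".legend.json")
  jsonlite::write_json(
    list(image_id = mask$image_id, legend = mask$legend),
    legend_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".legend.json"), simplifyVector = TRUE)
  legend <- as.data.frame(meta$legend, stringsAsFactors = FALSE)
  legend$label <- as.integer(legend$label)
  if (!"morphology" %in% names(legend)) legend$morphology <- NA_character_
  legend$morphology[legend$morphology == ""] <- NA_character_
  benthic_mask(matrix(as.integer(round(a * 255)), nrow(a), ncol(a)),
               image_id = meta$image_id, legend = legend)
}

#' Write / read a per-image feature table as CSV
#'
#' @param features data.frame of feature rows from [assemble_features()].
#' @param path CSV path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a study configuration from YAML
#'
#' Fields present in the file override [study_config()] defaults; nested
#' `elo` and `predictor` blocks override [elo_config()] /
#' [predictor_config()] fields.
#'
#' @param path YAML file path.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  elo_args <- y$elo %||% list()
  pred_args <- y$predictor %||% list()
  y$elo <- NULL; y$predictor <- NULL
  args <- c(y, list(elo = do.call(elo_config, elo_args),
                    predictor = do.call(predictor_config, pred_args)))
  do.call(study_config, args)
}
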