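#' Construct a habitat preset for the synthetic quadrat generator
#'
#' A preset states the benthic-community conditions of one habitat type:
#' hard-coral and rubble cover distributions (percent, as mean and SD of the
#' realized cover), the pool of coral growth forms present, the coral colour
#' palette, the structural-complexity-to-shadow scaling, and whether
#' restoration frames are present.
#'
#' Covers are drawn from a beta distribution on \[0, 100\] whose moments are
#' matched to `*_cover_mean` / `*_cover_sd`, so the realized covers reproduce
#' the stated field means exactly in expectation (a truncated normal at these
#' parameter values would not).
#'
#' @param name Habitat name: `"healthy"`, `"restored"` or `"degraded"`.
#' @param coral_cover_mean,coral_cover_sd Hard-coral cover mean and SD (%).
#' @param rubble_cover_mean,rubble_cover_sd Rubble cover mean and SD (%).
#' @param morphology_pool Subset of [coral_morphologies()] present.
#' @param palette List of coral colour archetypes (integer RGB triples).
#' @param shadow_scale Unitless scale (>= 0) mapping coral cover to the
#'   fraction of near-black shadow pixels in the rendered photograph.
#' @param frame_present Logical: render restoration-frame pixels.
#' @param frame_cover_pct Percent of pixels occupied by frame when present.
#' @return An object of class `habitat_preset`.
#' @seealso [default_habitat_presets()], [generate_quadrat()]
#' @export
habitat_preset <- function(name,
                           coral_cover_mean, coral_cover_sd,
                           rubble_cover_mean, rubble_cover_sd,
                           morphology_pool = coral_morphologies(),
                           palette = default_coral_palette(),
                           shadow_scale = 0.1,
                           frame_present = FALSE,
                           frame_cover_pct = 3) {
  p <- structure(
    list(name = name,
         coral_cover_mean = coral_cover_mean, coral_cover_sd = coral_cover_sd,
         rubble_cover_mean = rubble_cover_mean, rubble_cover_sd = rubble_cover_sd,
         morphology_pool = morphology_pool, palette = palette,
         shadow_scale = shadow_scale, frame_present = frame_present,
         frame_cover_pct = frame_cover_pct),
    class = "habitat_preset"
  )
  validate_preset(p)
  p
}

validate_preset <- function(p) {
  if (!inherits(p, "habitat_preset")) stop("not a habitat_preset object")
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid preset field '%s': %s", field, msg), call. = FALSE)
  }
  chk(is.character(p$name) && p$name %in% c("healthy", "restored", "degraded"),
      "name", "must be one of 'healthy', 'restored', 'degraded'")
  for (f in c("coral_cover_mean", "rubble_cover_mean")) {
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1 && p[[f]] >= 0 && p[[f]] <= 100,
        f, "must be a percent in [0, 100]")
  }
  for (f in c("coral_cover_sd", "rubble_cover_sd")) {
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1 && p[[f]] >= 0,
        f, "must be a non-negative SD in percent")
  }
  chk(length(p$morphology_pool) >= 1 &&
        all(p$morphology_pool %in% coral_morphologies()),
      "morphology_pool", "must be a non-empty subset of coral_morphologies()")
  chk(is.list(p$palette) && length(p$palette) >= 1 &&
        all(vapply(p$palette, function(x) {
          is.numeric(x) && length(x) == 3 && all(x >= 0) && all(x <= 255)
        }, logical(1))),
      "palette", "must be a list of RGB triples in [0, 255]")
  chk(is.numeric(p$shadow_scale) && length(p$shadow_scale) == 1 && p$shadow_scale >= 0,
      "shadow_scale", "must be a non-negative scalar")
  chk(is.logical(p$frame_present) && length(p$frame_present) == 1,
      "frame_present", "must be TRUE or FALSE")
  chk(is.numeric(p$frame_cover_pct) && p$frame_cover_pct >= 0 && p$frame_cover_pct <= 100,
      "frame_cover_pct", "must be a percent in [0, 100]")
  invisible(p)
}

#' Default coral colour archetypes
#'
#' Blue, green, yellow and brown coral colour variants, as RGB triples.
#' Brown variants fall in the "other" colour group of the default 64-bin
#' mapping (the named survey groups are black, blue, green, yellow, grey).
#'
#' @param drab If `TRUE`, return the reduced drab palette used for degraded
#'   habitat (brown variants plus one pale green).
#' @return List of integer RGB triples.
#' @export
default_coral_palette <- function(drab = FALSE) {
  if (drab) {
    return(list(brown1 = c(140L, 100L, 70L), brown2 = c(160L, 120L, 80L),
                palegreen = c(110L, 135L, 90L)))
  }
  list(blue1 = c(70L, 110L, 210L), blue2 = c(100L, 150L, 230L),
       green1 = c(90L, 175L, 95L), green2 = c(130L, 200L, 110L),
       yellow1 = c(225L, 200L, 70L), yellow2 = c(200L, 195L, 60L),
       brown1 = c(140L, 100L, 70L), brown2 = c(160L, 120L, 80L))
}

#' Default presets for the three habitat conditions of the study system
#'
#' Cover means and SDs are the field survey values for the study system:
#' healthy coral 70.46 +/- 23.02 and rubble 5.89 +/- 14.70; degraded coral
#' 11.71 +/- 21.27 and rubble 74.91 +/- 29.64; restored coral 61.32 +/- 22.01
#' and rubble 10.36 +/- 15.92 (percent). Healthy reefs carry all eight
#' growth forms and the full colour palette; restored reefs carry the
#' transplant-dominated growth forms, the full palette and metal frames;
#' degraded reefs carry few encrusting/massive remnants and a drab palette.
#'
#' @return Named list of three [habitat_preset()] objects.
#' @export
default_habitat_presets <- function() {
  list(
    healthy = habitat_preset(
      "healthy",
      coral_cover_mean = 70.46, coral_cover_sd = 23.02,
      rubble_cover_mean = 5.89, rubble_cover_sd = 14.70,
      morphology_pool = coral_morphologies(),
      palette = default_coral_palette(),
      shadow_scale = 0.11, frame_present = FALSE),
    restored = habitat_preset(
      "restored",
      coral_cover_mean = 61.32, coral_cover_sd = 22.01,
      rubble_cover_mean = 10.36, rubble_cover_sd = 15.92,
      morphology_pool = c("branching", "digitate", "foliose",
                          "massive", "submassive", "tabulate"),
      palette = default_coral_palette(),
      shadow_scale = 0.11, frame_present = TRUE),
    degraded = habitat_preset(
      "degraded",
      coral_cover_mean = 11.71, coral_cover_sd = 21.27,
      rubble_cover_mean = 74.91, rubble_cover_sd = 29.64,
      morphology_pool = c("encrusting", "massive", "submassive"),
      palette = default_coral_palette(drab = TRUE),
      shadow_scale = 0.08, frame_present = FALSE)
  )
}
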