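# Calibrated slide annotations and their quantification into p16 foci
# densities per 100 mm^2 of annotated lung tissue.

#' Construct a tissue region
#'
#' An annotated patch of lung parenchyma: one outer ring with optional holes
#' (e.g. airspaces excluded from the area measurement). Coordinates are
#' 0-based pixels, y down.
#'
#' @param outer_ring Vertex matrix of the outer boundary (>= 3 rows).
#' @param holes List of vertex matrices fully inside the outer ring.
#' @return A `tissue_region` object.
#' @export
tissue_region <- function(outer_ring, holes = list()) {
  outer_ring <- as_ring(outer_ring)
  holes <- lapply(holes, as_ring)
  outer_a <- ring_area(outer_ring)
  for (h in holes) {
    if (ring_area(h) >= outer_a) {
      stop("invalid geometry: hole area is not smaller than its outer ring",
           call. = FALSE)
    }
  }
  structure(list(outer_ring = outer_ring, holes = holes),
            class = "tissue_region")
}

#' Construct a focus mark
#'
#' A point annotation marking one p16-positive fibroblastic focus (polygonal
#' focus annotations are reduced to their centroid upstream).
#'
#' @param focus_id Unique identifier within the slide.
#' @param location Numeric `(x, y)` pixel coordinates.
#' @param note Optional free-text note.
#' @return A `focus_mark` object.
#' @export
focus_mark <- function(focus_id, location, note = NULL) {
  stopifnot(is.character(focus_id), nchar(focus_id) > 0,
            is.numeric(location), length(location) == 2)
  structure(list(focus_id = focus_id, location = as.numeric(location),
                 note = note),
            class = "focus_mark")
}

#' Construct a calibrated slide
#'
#' The unit of quantification: annotation geometry plus an isotropic
#' microns-per-pixel calibration. Anisotropic calibrations (length-2
#' `microns_per_pixel`) are rejected.
#'
#' @param slide_id Non-empty slide identifier.
#' @param microns_per_pixel Positive scalar, micrometres per pixel.
#' @param tissue_regions List of [tissue_region()] (may be empty).
#' @param focus_marks List of [focus_mark()] with unique ids.
#' @return A `calibrated_slide` object.
#' @export
calibrated_slide <- function(slide_id, microns_per_pixel,
                             tissue_regions = list(), focus_marks = list()) {
  if (!is.character(slide_id) || length(slide_id) != 1 || !nzchar(slide_id)) {
    stop("slide_id must be a non-empty string", call. = FALSE)
  }
  if (length(microns_per_pixel) != 1) {
    stop("calibration must be isotropic: a single microns-per-pixel value",
         call. = FALSE)
  }
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("microns_per_pixel must be a positive number", call. = FALSE)
  }
  stopifnot(all(vapply(tissue_regions, inherits, logical(1), "tissue_region")),
            all(vapply(focus_marks, inherits, logical(1), "focus_mark")))
  ids <- vapply(focus_marks, `[[`, character(1), "focus_id")
  if (anyDuplicated(ids)) {
    stop("focus ids must be unique within a slide", call. = FALSE)
  }
  structure(list(slide_id = slide_id,
                 microns_per_pixel = as.numeric(microns_per_pixel),
                 tissue_regions = tissue_regions,
                 focus_marks = focus_marks),
            class = "calibrated_slide")
}

ring_bbox <- function(ring) c(min(ring[, 1]), min(ring[, 2]),
                              max(ring[, 1]), max(ring[, 2]))

bbox_overlap <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

#' Annotated tissue area in mm^2
#'
#' Sum over regions of (outer area minus hole areas) in pixels squared,
#' converted with the squared calibration. Regions are summed without polygon
#' union -- the input contract expects disjoint annotations; overlapping
#' bounding boxes trigger a warning.
#'
#' @param slide A [calibrated_slide()].
#' @return Tissue area in mm^2.
#' @export
tissue_area_mm2 <- function(slide) {
  stopifnot(inherits(slide, "calibrated_slide"))
  regions <- slide$tissue_regions
  if (length(regions) >= 2) {
    boxes <- lapply(regions, function(r) ring_bbox(r$outer_ring))
    for (i in seq_along(boxes)) {
      for (j in seq_len(i - 1)) {
        if (bbox_overlap(boxes[[i]], boxes[[j]])) {
          warning(sprintf(
            "slide %s: tissue regions %d and %d have overlapping bounding boxes; areas are summed without union",
            slide$slide_id, j, i), call. = FALSE)
        }
      }
    }
  }
  px2 <- sum(vapply(regions, function(r) {
    ring_area(r$outer_ring) - sum(vapply(r$holes, ring_area, numeric(1)))
  }, numeric(1)))
  px2 * slide$microns_per_pixel^2 / 1e6
}

#' Dichotomize a foci density
#'
#' Cases at or below the cutoff are p16-low; above it, p16-high. The default
#' cutoff of 2.1 foci per 100 mm^2 is a configuration value so that an
#' ROC-derived cutoff (see [roc_curve()]) can replace it.
#'
#' @param density Non-negative foci density per 100 mm^2.
#' @param cutoff Positive dichotomization value (default 2.1).
#' @return `"low"` or `"high"` (vectorized over `density`).
#' @export
classify_density <- function(density, cutoff = 2.1) {
  stopifnot(is.numeric(density), is.numeric(cutoff), cutoff > 0)
  if (any(density < 0)) stop("density must be non-negative", call. = FALSE)
  ifelse(density > cutoff, "high", "low")
}

#' Quantify one slide
#'
#' Counts focus marks falling inside any tissue region (boundary inclusive),
#' measures the annotated tissue area, and reports the density per 100 mm^2
#' with its p16-low/high class. Marks outside tissue are tallied separately
#' and reported via a message.
#'
#' @param slide A [calibrated_slide()].
#' @param cutoff Density dichotomization value (default 2.1).
#' @return A `slide_quant` list: `slide_id`, `n_foci`, `n_foci_excluded`,
#'   `tissue_area_mm2`, `density` (per 100 mm^2), `p16_class`.
#' @export
quantify_slide <- function(slide, cutoff = 2.1) {
  stopifnot(inherits(slide, "calibrated_slide"))
  area <- tissue_area_mm2(slide)
  in_tissue <- vapply(slide$focus_marks, function(m) {
    any(vapply(slide$tissue_regions, function(r) point_in_region(m$location, r),
               logical(1)))
  }, logical(1))
  n_in <- sum(in_tissue)
  n_out <- length(in_tissue) - n_in
  if (n_out > 0) {
    message(sprintf("slide %s: %d focus mark(s) outside annotated tissue excluded",
                    slide$slide_id, n_out))
  }
  if (area <= 0) {
    if (length(slide$focus_marks) > 0) {
      stop(sprintf("slide %s: foci marked but annotated tissue area is zero",
                   slide$slide_id), call. = FALSE)
    }
    warning(sprintf("slide %s: zero tissue area and no in-tissue foci; density set to 0",
                    slide$slide_id), call. = FALSE)
    density <- 0
  } else {
    density <- 100 * n_in / area
  }
  structure(list(slide_id = slide$slide_id,
                 n_foci = n_in,
                 n_foci_excluded = n_out,
                 tissue_area_mm2 = area,
                 density = density,
                 p16_class = classify_density(density, cutoff)),
            class = "slide_quant")
}

#' @export
print.slide_quant <- function(x, ...) {
  cat(sprintf("Slide %s: %d foci in %.3f mm^2 tissue -> %.2f per 100 mm^2 (p16-%s)",
              x$slide_id, x$n_foci, x$tissue_area_mm2, x$density, x$p16_class))
  if (x$n_foci_excluded > 0) cat(sprintf("; %d mark(s) excluded", x$n_foci_excluded))
  cat("\n")
  invisible(x)
}

#' Quantify a list of slides into a table
#'
#' @param slides List of [calibrated_slide()].
#' @param cutoff Density dichotomization value.
#' @return Data frame with one row per slide (`slide_id`, `n_foci`,
#'   `n_foci_excluded`, `tissue_area_mm2`, `density_per_100mm2`, `p16_class`).
#' @export
quantify_slides <- function(slides, cutoff = 2.1) {
  rows <- lapply(slides, function(s) {
    q <- quantify_slide(s, cutoff)
    data.frame(slide_id = q$slide_id, n_foci = q$n_foci,
               n_foci_excluded = q$n_foci_excluded,
               tissue_area_mm2 = q$tissue_area_mm2,
               density_per_100mm2 = q$density,
               p16_class = q$p16_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
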