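# GeoJSON-dialect reader/writer for slide annotations, following the common
# whole-slide export convention: tissue regions are Polygon features with
# properties$classification$name == "Tissue", foci are Point features
# classified "Focus", and the calibration sits in a top-level
# "microns_per_pixel" property (or is supplied by the caller).

feature_class <- function(feature) {
  cls <- feature$properties$classification
  if (is.list(cls)) cls$name %||% NA_character_
  else if (is.character(cls)) cls
  else NA_character_
}

coords_to_ring <- function(coords) {
  # jsonlite may parse a ring as a matrix or as a list of pairs
  if (is.matrix(coords)) return(as_ring(coords))
  as_ring(do.call(rbind, lapply(coords, function(p) as.numeric(unlist(p)))))
}

#' Read slide annotations from GeoJSON
#'
#' Parses a FeatureCollection containing `Polygon` tissue features (first ring
#' = outer boundary, further rings = holes) and `Point` focus features.
#'
#' @param path GeoJSON file path.
#' @param microns_per_pixel Calibration override; required when the file has
#'   no top-level `microns_per_pixel` property.
#' @param slide_id Slide identifier; defaults to the file's `slide_id`
#'   property, else the file base name.
#' @return A [calibrated_slide()].
#' @export
read_slide_geojson <- function(path, microns_per_pixel = NULL, slide_id = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection")) {
    stop(sprintf("%s: not a GeoJSON FeatureCollection", path), call. = FALSE)
  }
  mpp <- microns_per_pixel %||% doc$microns_per_pixel
  if (is.null(mpp)) {
    stop(sprintf("%s: no microns_per_pixel property and none supplied", path),
         call. = FALSE)
  }
  sid <- slide_id %||% doc$slide_id %||% sub("\\.[^.]*$", "", basename(path))

  regions <- list()
  marks <- list()
  n_focus <- 0L
  for (feature in doc$features) {
    cls <- feature_class(feature)
    gtype <- feature$geometry$type
    if (identical(gtype, "Polygon") && identical(cls, "Tissue")) {
      rings <- lapply(feature$geometry$coordinates, coords_to_ring)
      regions[[length(regions) + 1L]] <-
        tissue_region(rings[[1]], holes = rings[-1])
    } else if (identical(gtype, "Point") && identical(cls, "Focus")) {
      n_focus <- n_focus + 1L
      fid <- feature$properties$focus_id %||% sprintf("focus_%03d", n_focus)
      marks[[length(marks) + 1L]] <-
        focus_mark(as.character(fid),
                   as.numeric(unlist(feature$geometry$coordinates)),
                   note = feature$properties$note)
    }
    # other classifications (e.g. plain annotations) are ignored
  }
  calibrated_slide(sid, as.numeric(mpp), regions, marks)
}

ring_to_coords <- function(ring) {
  closed <- rbind(ring, ring[1, , drop = FALSE])  # GeoJSON rings are closed
  lapply(seq_len(nrow(closed)), function(i) as.numeric(closed[i, ]))
}

#' Write slide annotations to GeoJSON
#'
#' Inverse of [read_slide_geojson()]; used by the synthetic-slide generator
#' and for round-tripping annotations.
#'
#' @param slide A [calibrated_slide()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_slide_geojson <- function(slide, path) {
  stopifnot(inherits(slide, "calibrated_slide"))
  features <- c(
    lapply(slide$tissue_regions, function(r) {
      list(type = "Feature",
           properties = list(classification = list(name = "Tissue")),
           geometry = list(type = "Polygon",
                           coordinates = c(list(ring_to_coords(r$outer_ring)),
                                           lapply(r$holes, ring_to_coords))))
    }),
    lapply(slide$focus_marks, function(m) {
      list(type = "Feature",
           properties = list(classification = list(name = "Focus"),
                             focus_id = m$focus_id),
           geometry = list(type = "Point", coordinates = m$location))
    })
  )
  doc <- list(type = "FeatureCollection",
              slide_id = slide$slide_id,
              microns_per_pixel = slide$microns_per_pixel,
              features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
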