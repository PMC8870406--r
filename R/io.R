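# File formats: 32-bit TIFF phase maps (with JSON sidecar metadata), 16-bit
# label-image TIFFs, VGG Image Annotator (VIA) JSON polygon annotations and
# dataset manifests.
#
# TIFF samples are stored in [0, 1]; phase values are mapped linearly by
# stored = (phase + pi) / (2 * pi), which quantizes at ~1.5e-9 rad for
# 32-bit samples. The mapping, pixel size and frame order are recorded in a
# `.json` sidecar next to each TIFF.

phase_to_unit <- function(phase) (phase + pi) / (2 * pi)
unit_to_phase <- function(u) u * 2 * pi - pi

sidecar_path <- function(path) paste0(path, ".json")

#' Write a phase map as 32-bit TIFF
#'
#' @param map a [phase_map()].
#' @param path output file path (`.tif`); a JSON sidecar `<path>.json`
#'   records the pixel size and the linear sample mapping.
#' @return `path`, invisibly.
#' @export
write_phase_tiff <- function(map, path) {
  assert_that(inherits(map, "phase_map"), "map must be a phase_map", format_error)
  assert_that(all(map$phase > -pi & map$phase <= pi),
              "phase must lie in (-pi, pi] for TIFF storage", format_error)
  tiff::writeTIFF(phase_to_unit(map$phase), path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(kind = "phase_map", units = "radians",
         pixel_size_um = map$pixel_size,
         sample_mapping = "phase = stored * 2*pi - pi"),
    sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a phase map written by [write_phase_tiff()]
#'
#' @param path TIFF file path.
#' @return a [phase_map()].
#' @export
read_phase_tiff <- function(path) {
  u <- tiff::readTIFF(path)
  if (length(dim(u)) == 3L) u <- u[, , 1L]
  px <- 0.5
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    if (!is.null(meta$pixel_size_um)) px <- as.numeric(meta$pixel_size_um)
  }
  phase_map(unit_to_phase(u), pixel_size = px)
}

#' Write a four-frame intensity stack as a 4-page TIFF
#'
#' Pages follow modulator shift order 0, pi/2, pi, 3*pi/2. Intensities are
#' stored scaled by their maximum; the scale is recorded in the sidecar.
#'
#' @param stack a [frame_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(stack, path) {
  assert_that(inherits(stack, "frame_stack"), "stack must be a frame_stack",
              format_error)
  top <- max(1e-300, max(vapply(stack$frames, max, numeric(1L))))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / top), path,
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(kind = "frame_stack", page_order = "shift 0, pi/2, pi, 3pi/2",
         intensity_scale = top),
    sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a frame stack written by [write_frames_tiff()]
#' @param path TIFF file path.
#' @return a [frame_stack()].
#' @export
read_frames_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  assert_that(length(pages) == 4L, "frame-stack TIFF must have 4 pages", format_error)
  scale <- 1
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    if (!is.null(meta$intensity_scale)) scale <- as.numeric(meta$intensity_scale)
  }
  frame_stack(lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p * scale
  }))
}

#' Write an instance label image as 16-bit TIFF
#'
#' @param labels integer matrix; 0 = background, k = instance k (k <= 65535).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  assert_that(is.matrix(labels) && all(labels >= 0) && all(labels <= 65535),
              "labels must be an integer matrix in [0, 65535]", format_error)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Read an instance label image written by [write_label_tiff()]
#' @param path TIFF file path.
#' @return integer matrix of instance labels.
#' @export
read_label_tiff <- function(path) {
  u <- tiff::readTIFF(path)
  if (length(dim(u)) == 3L) u <- u[, , 1L]
  matrix(as.integer(round(u * 65535)), nrow(u), ncol(u))
}

# ---- VGG Image Annotator (VIA) JSON dialect ------------------------------

# VIA stores polygons with x = column and y = row, here kept 0-based.
via_region <- function(polygon, class_label) {
  list(shape_attributes = list(name = "polygon",
                               all_points_x = round(polygon[, 2L], 2),
                               all_points_y = round(polygon[, 1L], 2)),
       region_attributes = list(class = class_label))
}

#' Write VIA-dialect polygon annotations for a set of cores
#'
#' One entry per core, keyed VIA-style by `filename + size`, with polygon
#' `shape_attributes` and a `region_attributes$class` of `"cancer"` or
#' `"normal"`. Instances without a stored polygon are polygonized from
#' their masks.
#'
#' @param truths list of [core_ground_truth()] objects.
#' @param path output JSON path.
#' @param filenames optional character vector of image filenames (default
#'   `<core_id>.tif`).
#' @return `path`, invisibly.
#' @export
write_via_json <- function(truths, path, filenames = NULL) {
  if (inherits(truths, "core_ground_truth")) truths <- list(truths)
  if (is.null(filenames)) {
    filenames <- vapply(truths, function(t) paste0(t$core_id, ".tif"), character(1L))
  }
  out <- list()
  for (i in seq_along(truths)) {
    t <- truths[[i]]
    regions <- lapply(t$instances, function(inst) {
      poly <- inst$polygon
      if (is.null(poly)) poly <- mask_polygon(inst$mask)
      via_region(poly, inst$class_label)
    })
    size <- prod(t$image_shape)  # stand-in for byte size, per VIA keying habit
    out[[paste0(filenames[i], size)]] <- list(
      filename = filenames[i], size = size, regions = regions,
      file_attributes = stats::setNames(list(), character(0)))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read VIA-dialect polygon annotations
#'
#' @param path JSON file path.
#' @return named list (by filename) of data holding `filename` and
#'   `regions`: each region a list with `polygon` (n x 2 row/col matrix)
#'   and `class_label`.
#' @export
read_via_json <- function(path) {
  raw <- jsonlite::read_json(path)
  out <- lapply(raw, function(entry) {
    regions <- lapply(entry$regions, function(rg) {
      sa <- rg$shape_attributes
      assert_that(identical(sa$name, "polygon"), "only polygon regions supported",
                  format_error)
      poly <- cbind(row = as.numeric(unlist(sa$all_points_y)),
                    col = as.numeric(unlist(sa$all_points_x)))
      list(polygon = poly, class_label = rg$region_attributes$class)
    })
    list(filename = entry$filename, regions = regions)
  })
  stats::setNames(out, vapply(out, `[[`, character(1L), "filename"))
}

#' Rebuild ground-truth instances from VIA annotations
#'
#' @param via_entry one element of [read_via_json()]'s result.
#' @param image_shape integer `(rows, cols)` to rasterize into.
#' @param core_id core identifier.
#' @param core_label core-level label; default majority vote of the regions.
#' @return a [core_ground_truth()].
#' @export
truth_from_via <- function(via_entry, image_shape, core_id = via_entry$filename,
                           core_label = NULL) {
  claimed <- matrix(FALSE, image_shape[1L], image_shape[2L])
  instances <- lapply(via_entry$regions, function(rg) {
    m <- rasterize_polygon(rg$polygon, image_shape)
    m <- m & !claimed
    claimed <<- claimed | m
    gland_instance(m, rg$class_label, score = 1, polygon = rg$polygon)
  })
  labels <- vapply(instances, function(x) x$class_label, character(1L))
  if (is.null(core_label)) {
    core_label <- if (length(labels) && mean(labels == "cancer") > 0.5) "cancer"
    else "normal"
  }
  core_ground_truth(instances, core_label, core_id, image_shape)
}

# Polygonize a mask: outer contour of the hole-filled mask, (row, col) 0-based.
mask_polygon <- function(mask) {
  m <- EBImage::fillHull(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  oc <- EBImage::ocontour(m)[[1L]]
  # EBImage returns (x, y) = (row-index-1, col-index-1) for matrix input
  cbind(row = oc[, 1L], col = oc[, 2L])
}
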