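# Synthetic tissue-microarray cores with ground-truth gland instances.
#
# A core is a circular tissue footprint of textured stroma containing ring-
# shaped epithelial glands around lumens. Normal glands have smooth, regular
# boundaries; cancer glands have rough, eroded, occasionally fused ones. The
# single roughness knob (`irregularity`) drives a radial Fourier perturbation
# of an ellipse: the default scale is 512 x 512 px at 2 px/um (~1 mm core),
# and all geometry scales with image size.

#' Gland geometry and phase specification
#'
#' @param center numeric `(row, col)` of the gland center, 0-based pixels.
#' @param base_radius mean gland radius in pixels; > 0.
#' @param class_label `"normal"` or `"cancer"`.
#' @param irregularity boundary roughness amplitude in `[0, 1]`; 0 gives an
#'   exact circle.
#' @param lumen_fraction lumen radius as a fraction of the gland radius, in
#'   (0, 1).
#' @param phase_amplitude peak epithelial phase, radians, in (0, pi).
#' @return an object of class `gland_spec`.
#' @export
gland_spec <- function(center, base_radius, class_label = c("normal", "cancer"),
                       irregularity = 0.1, lumen_fraction = 0.45,
                       phase_amplitude = 1.6) {
  class_label <- match.arg(class_label)
  assert_that(is.numeric(center) && length(center) == 2L && all(is.finite(center)),
              "center must be (row, col)")
  assert_that(is_scalar_number(base_radius) && base_radius > 0,
              "base_radius must be > 0")
  assert_that(is_scalar_number(irregularity) && irregularity >= 0 && irregularity <= 1,
              "irregularity must be in [0, 1]")
  assert_that(is_scalar_number(lumen_fraction) && lumen_fraction > 0 &&
                lumen_fraction < 1, "lumen_fraction must be in (0, 1)")
  assert_that(is_scalar_number(phase_amplitude) && phase_amplitude > 0 &&
                phase_amplitude < pi, "phase_amplitude must be in (0, pi)")
  structure(list(center = as.numeric(center), base_radius = base_radius,
                 class_label = class_label, irregularity = irregularity,
                 lumen_fraction = lumen_fraction,
                 phase_amplitude = phase_amplitude),
            class = "gland_spec")
}

#' Sample a gland boundary polygon
#'
#' Draws a closed boundary as a radial Fourier perturbation of a circle:
#' harmonics 2..8 receive Gaussian amplitudes decaying with harmonic order
#' and scaled by `irregularity` (harmonic 2 supplies ellipticity; the higher
#' orders supply the lobed, eroded look of malignant glands). The radius
#' profile is renormalized so its mean equals `base_radius` exactly; at
#' `irregularity = 0` the boundary is an exact circle.
#'
#' @param spec a [gland_spec()].
#' @param seed integer seed; identical seeds give identical polygons.
#' @param n_vertices number of boundary vertices.
#' @return numeric `n_vertices x 2` matrix of (row, col) vertices, 0-based,
#'   closed implicitly.
#' @export
sample_gland_shape <- function(spec, seed = NULL, n_vertices = 96L) {
  assert_that(inherits(spec, "gland_spec"), "spec must be a gland_spec")
  assert_that(is_scalar_number(n_vertices) && n_vertices >= 8,
              "n_vertices must be >= 8")
  with_local_seed(seed, {
    k <- 2:8
    sk <- 0.85 / k^1.1
    a <- stats::rnorm(length(k), 0, sk)
    b <- stats::rnorm(length(k), 0, sk)
    theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
    g <- drop(cos(outer(theta, k)) %*% a + sin(outer(theta, k)) %*% b)
    r <- pmax(1 + spec$irregularity * g, 0.2)
    r <- r / mean(r) * spec$base_radius
    cbind(row = spec$center[1L] + r * sin(theta),
          col = spec$center[2L] + r * cos(theta))
  })
}

# Scale a polygon radially about a center point.
scale_polygon <- function(poly, center, factor) {
  sweep(sweep(poly, 2L, center, "-") * factor, 2L, center, "+")
}

#' Single gland instance
#'
#' A detected or annotated gland: full-image binary mask, tight bounding box,
#' class label and confidence score.
#'
#' @param mask logical matrix, full image size, non-empty.
#' @param class_label `"cancer"` or `"normal"`.
#' @param score confidence in `[0, 1]` (1 for ground truth).
#' @param polygon optional boundary polygon (n x 2, 0-based row/col).
#' @return an object of class `gland_instance` with the tight half-open
#'   `bbox` `(r0, c0, r1, c1)` computed from the mask.
#' @export
gland_instance <- function(mask, class_label, score = 1, polygon = NULL) {
  assert_that(is.matrix(mask) && is.logical(mask), "mask must be a logical matrix",
              format_error)
  assert_that(any(mask), "instance mask must be non-empty", format_error)
  assert_that(class_label %in% c("cancer", "normal"),
              "class_label must be 'cancer' or 'normal'", format_error)
  assert_that(is_scalar_number(score) && score >= 0 && score <= 1,
              "score must be in [0, 1]")
  structure(list(mask = mask, bbox = mask_bbox(mask), class_label = class_label,
                 score = score, polygon = polygon),
            class = "gland_instance")
}

#' Per-core ground truth
#'
#' @param instances list of [gland_instance()] objects.
#' @param core_label `"cancer"` or `"normal"` core-level diagnosis.
#' @param core_id character identifier.
#' @param image_shape integer `(rows, cols)`.
#' @return an object of class `core_ground_truth`.
#' @export
core_ground_truth <- function(instances, core_label, core_id, image_shape) {
  assert_that(core_label %in% c("cancer", "normal"),
              "core_label must be 'cancer' or 'normal'", format_error)
  claimed <- matrix(0L, image_shape[1L], image_shape[2L])
  for (inst in instances) {
    assert_that(inherits(inst, "gland_instance"), "instances must be gland_instance")
    assert_that(all(dim(inst$mask) == image_shape),
                "instance mask must fit image_shape", format_error)
    claimed <- claimed + inst$mask
  }
  assert_that(all(claimed <= 1L), "instance masks must not overlap", format_error)
  structure(list(instances = instances, core_label = core_label,
                 core_id = core_id, image_shape = as.integer(image_shape)),
            class = "core_ground_truth")
}

#' Label image of a core's ground truth
#'
#' @param truth a [core_ground_truth()].
#' @return integer matrix; 0 = background, k = instance k.
#' @export
label_image <- function(truth) {
  lab <- matrix(0L, truth$image_shape[1L], truth$image_shape[2L])
  for (k in seq_along(truth$instances)) lab[truth$instances[[k]]$mask] <- k
  lab
}

default_stroma_params <- function() {
  list(mean = 0.35, sd = 0.10, corr = 8, background_sd = 0.02, lumen_phase = 0.08)
}

#' Render a synthetic core phase map with ground truth
#'
#' Composites gland rings over textured stroma inside a circular tissue
#' footprint. Stroma is low-pass-filtered Gaussian noise (tunable spatial
#' correlation length) with a lower mean phase than the epithelial rings;
#' cancer rings additionally receive multiplicative erosion texture so their
#' edges are fainter and less continuous. Each instance mask is the
#' rasterized gland polygon minus its lumen; when glands touch, pixels
#' already claimed by an earlier instance are trimmed from later ones, and a
#' later gland overlapping beyond `max_overlap` of its ring raises a
#' generation error.
#'
#' @param specs list of [gland_spec()] objects (may be empty).
#' @param shape integer `(rows, cols)`, at least 64 x 64.
#' @param stroma_params list with `mean`, `sd`, `corr` (correlation length,
#'   px), `background_sd` and `lumen_phase`; see defaults.
#' @param seed integer seed controlling boundary draws and textures.
#' @param core_id identifier stored in the ground truth.
#' @param core_label core-level label; default: the common label of `specs`
#'   (majority on a mix; `"normal"` for an empty core).
#' @param max_overlap maximum tolerated fraction of a gland ring overlapping
#'   previously placed glands.
#' @param pixel_size micrometres per pixel recorded in the phase map.
#' @return list with `phase` (a [phase_map()]) and `truth`
#'   (a [core_ground_truth()]).
#' @export
render_core <- function(specs, shape = c(512L, 512L),
                        stroma_params = default_stroma_params(), seed = NULL,
                        core_id = "core", core_label = NULL, max_overlap = 0.25,
                        pixel_size = 0.5) {
  assert_that(length(shape) == 2L && all(shape >= 64L),
              "shape must be at least 64 x 64")
  sp <- utils::modifyList(default_stroma_params(), as.list(stroma_params))
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  labels <- vapply(specs, function(s) s$class_label, character(1L))
  if (is.null(core_label)) {
    core_label <- if (length(labels) && mean(labels == "cancer") > 0.5) "cancer"
    else "normal"
  }
  with_local_seed(seed, {
    # stroma texture: low-pass-filtered noise, normalized to (mean, sd)
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
    tex <- EBImage::gblur(z, sigma = sp$corr)
    tex <- (tex - mean(tex)) / stats::sd(tex)
    stroma <- pmax(sp$mean + sp$sd * tex, 0.02)
    # fine texture reused inside epithelial rings
    fine <- EBImage::gblur(matrix(stats::rnorm(nr * nc), nr, nc), sigma = 2)
    fine <- (fine - mean(fine)) / stats::sd(fine)

    ctr <- (c(nr, nc) - 1) / 2
    rows <- matrix(seq_len(nr) - 1, nr, nc)
    cols <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
    footprint <- (rows - ctr[1L])^2 + (cols - ctr[2L])^2 <=
      (0.47 * min(nr, nc))^2
    phase <- matrix(stats::rnorm(nr * nc, 0, sp$background_sd), nr, nc)
    phase[footprint] <- stroma[footprint]

    claimed <- matrix(FALSE, nr, nc)
    instances <- list()
    for (i in seq_along(specs)) {
      spec <- specs[[i]]
      outer_poly <- sample_gland_shape(spec)
      lumen_poly <- scale_polygon(outer_poly, spec$center, spec$lumen_fraction)
      ring <- rasterize_polygon(outer_poly, c(nr, nc)) &
        !rasterize_polygon(lumen_poly, c(nr, nc))
      n_ring <- sum(ring)
      if (n_ring == 0L) generation_error(sprintf("gland %d rasterizes to nothing", i))
      ov <- sum(ring & claimed) / n_ring
      if (ov > max_overlap) {
        generation_error(sprintf("gland %d overlaps existing glands by %.0f%%",
                                 i, 100 * ov))
      }
      ring <- ring & !claimed
      claimed <- claimed | ring
      amp <- spec$phase_amplitude
      ep <- amp * (0.85 + 0.20 * fine[ring])
      if (spec$class_label == "cancer") {
        # erosion texture: fainter, less pronounced edges
        ep <- ep * pmin(pmax(0.80 + 0.30 * fine[ring], 0.45), 1.1)
      }
      phase[ring] <- pmin(pmax(ep, 0.05), pi - 1e-6)
      lumen_px <- rasterize_polygon(lumen_poly, c(nr, nc)) & !claimed
      phase[lumen_px] <- pmax(sp$lumen_phase +
                                0.02 * fine[lumen_px], 0.01)
      instances[[length(instances) + 1L]] <-
        gland_instance(ring, spec$class_label, score = 1, polygon = outer_poly)
    }
    # mild optical smoothing so edges are not pixel-sharp
    phase <- EBImage::gblur(phase, sigma = 1)
    phase <- pmin(pmax(phase, -pi + 1e-9), pi)
    list(phase = phase_map(phase, pixel_size = pixel_size),
         truth = core_ground_truth(instances, core_label, core_id, c(nr, nc)))
  })
}

#' Sample gland specifications for a core preset
#'
#' Draws per-gland geometry from class presets ("normal": smooth boundaries,
#' wide lumens, strong rings; "cancer": rough boundaries, narrow lumens,
#' fainter rings) and places centers by dart throwing inside the tissue
#' footprint with center spacing at least the sum of base radii.
#'
#' @param class_label `"normal"` or `"cancer"`; every gland in the preset
#'   carries this label.
#' @param shape image shape `(rows, cols)`.
#' @param n_glands number of glands, or `NULL` to draw uniformly from
#'   `4..12` (the density a ~1 mm core supports at this scale).
#' @param seed integer seed.
#' @return list of [gland_spec()] objects.
#' @export
core_preset <- function(class_label = c("normal", "cancer"),
                        shape = c(512L, 512L), n_glands = NULL, seed = NULL) {
  class_label <- match.arg(class_label)
  side <- min(shape)
  with_local_seed(seed, {
    if (is.null(n_glands)) n_glands <- sample(4:12, 1L)
    radii <- stats::runif(n_glands, 0.055, 0.10) * side
    ctr <- (shape - 1) / 2
    r_foot <- 0.47 * side
    centers <- matrix(NA_real_, 0L, 2L)
    kept <- integer(0)
    for (g in seq_len(n_glands)) {
      placed <- FALSE
      for (try in seq_len(250L)) {
        u <- stats::runif(1L, 0, 2 * pi)
        d <- sqrt(stats::runif(1L)) * (r_foot - radii[g] - 3)
        cand <- ctr + d * c(sin(u), cos(u))
        ok <- TRUE
        if (length(kept)) {
          dist <- sqrt(rowSums(sweep(centers, 2L, cand)^2))
          ok <- all(dist >= 1.12 * (radii[kept] + radii[g]) + 2)
        }
        if (ok) {
          centers <- rbind(centers, cand)
          kept <- c(kept, g)
          placed <- TRUE
          break
        }
      }
      if (!placed) next  # core is full; accept fewer glands
    }
    lapply(seq_along(kept), function(k) {
      g <- kept[k]
      if (class_label == "normal") {
        gland_spec(centers[k, ], radii[g], "normal",
                   irregularity = stats::runif(1L, 0.03, 0.15),
                   lumen_fraction = stats::runif(1L, 0.40, 0.55),
                   phase_amplitude = stats::runif(1L, 1.3, 2.2))
      } else {
        gland_spec(centers[k, ], radii[g], "cancer",
                   irregularity = stats::runif(1L, 0.45, 0.85),
                   lumen_fraction = stats::runif(1L, 0.12, 0.35),
                   phase_amplitude = stats::runif(1L, 1.0, 1.8))
      }
    })
  })
}

#' Boundary-roughness (circularity) statistic of a mask
#'
#' `perimeter^2 / (4 * pi * area)` of the hole-filled mask, with the
#' perimeter measured as the Euclidean length of the 8-connected outer
#' contour chain. A disk scores close to 1 (about 1.1 for digitized disks);
#' rough, lobed boundaries score substantially higher. This is the simple
#' morphological feature that separates normal from cancer glands.
#'
#' @param mask logical or 0/1 matrix of one instance.
#' @return scalar roughness statistic (>= ~1).
#' @export
roughness_statistic <- function(mask) {
  m <- EBImage::fillHull(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  area <- sum(m)
  if (area == 0L) return(NA_real_)
  oc <- EBImage::ocontour(m)[[1L]]
  if (nrow(oc) < 3L) return(1)
  d <- sqrt(rowSums((oc - rbind(oc[-1L, , drop = FALSE], oc[1L, , drop = FALSE]))^2))
  sum(d)^2 / (4 * pi * area)
}
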