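# SLIM optics: forward simulation of the four phase-shifted intensity frames
# and quantitative-phase retrieval.
#
# The interferometric image model at every pixel is
#   I_k = |U0|^2 * (1 + beta^2 + 2 * beta * cos(dphi + k*pi/2)),  k = 0..3,
# where U0 is the unscattered field, beta = |U1|/|U0| the scattered-to-
# unscattered amplitude ratio and dphi the phase lag of the scattered
# component. The specimen phase is the argument of the total field,
#   phi = atan2(beta * sin(dphi), 1 + beta * cos(dphi)).
# Retrieval inverts the four-frame algebra exactly:
#   G = sqrt((I0-I2)^2 + (I3-I1)^2) = 4|U0|^2 beta
#   S = (I0+I1+I2+I3)/4            = |U0|^2 (1 + beta^2)
# so |U0|^2 and |U1|^2 are the two roots of x^2 - S x + (G/4)^2 = 0; the
# unscattered component dominates in transparent tissue and takes the larger
# root.

#' Quantitative phase map
#'
#' Container for a 2D field of specimen-induced phase delay.
#'
#' @param phase numeric matrix, radians; values in (-pi, pi] unless the map is
#'   explicitly marked as unwrapped.
#' @param pixel_size pixel pitch in micrometres per pixel.
#' @param unwrapped logical; if `FALSE` (default) values must lie in (-pi, pi].
#' @return an object of class `phase_map`.
#' @export
phase_map <- function(phase, pixel_size = 0.5, unwrapped = FALSE) {
  assert_that(is.matrix(phase) && is.numeric(phase), "phase must be a numeric matrix",
              format_error)
  assert_that(all(is.finite(phase)), "phase values must be finite", format_error)
  if (!unwrapped) {
    assert_that(all(phase > -pi - 1e-12 & phase <= pi + 1e-12),
                "wrapped phase must lie in (-pi, pi]", format_error)
  }
  assert_that(is_scalar_number(pixel_size) && pixel_size > 0,
              "pixel_size must be a positive number")
  structure(list(phase = phase, pixel_size = pixel_size, unwrapped = unwrapped),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px, %.3g um/px, range [%.3f, %.3f] rad\n",
              nrow(x$phase), ncol(x$phase), x$pixel_size,
              min(x$phase), max(x$phase)))
  invisible(x)
}

#' @export
dim.phase_map <- function(x) dim(x$phase)

as_phase_matrix <- function(x) {
  if (inherits(x, "phase_map")) x$phase
  else if (is.matrix(x) && is.numeric(x)) x
  else format_error("expected a phase_map or numeric matrix")
}

#' Interferometric field model
#'
#' Per-pixel description of the two-component field from which the four
#' phase-shifted frames are generated.
#'
#' @param u0_intensity unscattered intensity |U0|^2; scalar or matrix, >= 0.
#' @param beta amplitude ratio |U1|/|U0|; scalar or matrix, >= 0.
#' @param delta_phi phase lag of the scattered component, radians; scalar or
#'   matrix.
#' @return an object of class `field_model` with matrix fields of a common
#'   shape.
#' @export
field_model <- function(u0_intensity, beta, delta_phi) {
  shapes <- lapply(list(u0_intensity, beta, delta_phi), function(f)
    if (is.matrix(f)) dim(f) else NULL)
  shapes <- Filter(Negate(is.null), shapes)
  assert_that(length(shapes) > 0L, "at least one field must be a matrix")
  shp <- shapes[[1L]]
  for (s in shapes) assert_that(all(s == shp), "field shapes must match", format_error)
  expand <- function(f) if (is.matrix(f)) f else matrix(f, shp[1L], shp[2L])
  u0 <- expand(u0_intensity); b <- expand(beta); dp <- expand(delta_phi)
  assert_that(all(is.finite(u0)) && all(u0 >= 0), "u0_intensity must be finite and >= 0")
  assert_that(all(is.finite(b)) && all(b >= 0), "beta must be finite and >= 0")
  assert_that(all(is.finite(dp)), "delta_phi must be finite")
  structure(list(u0_intensity = u0, beta = b, delta_phi = dp), class = "field_model")
}

#' Specimen phase of a field model
#'
#' The argument of the total field `U0 + U1`, i.e. the phase a perfect
#' retrieval should recover.
#'
#' @param model a [field_model()].
#' @return numeric matrix of phase values in (-pi, pi].
#' @export
model_phase <- function(model) {
  assert_that(inherits(model, "field_model"), "model must be a field_model")
  atan2(model$beta * sin(model$delta_phi), 1 + model$beta * cos(model$delta_phi))
}

#' Simulate the four phase-shifted SLIM frames
#'
#' Generates the intensity frames at modulator shifts 0, pi/2, pi, 3*pi/2.
#' Optional detector noise is additive Gaussian, truncated at zero so
#' intensities stay non-negative.
#'
#' @param model a [field_model()].
#' @param noise_sd standard deviation of additive intensity noise (detector
#'   units); 0 for noiseless frames.
#' @param seed integer seed for the noise draw, or `NULL`.
#' @param poisson if `TRUE`, Poisson shot noise (frames used as expected
#'   counts) replaces the Gaussian model.
#' @return an object of class `frame_stack`: list with `frames` (list of four
#'   matrices in shift order) and `shifts`.
#' @export
simulate_frames <- function(model, noise_sd = 0, seed = NULL, poisson = FALSE) {
  assert_that(inherits(model, "field_model"), "model must be a field_model")
  assert_that(is_scalar_number(noise_sd) && noise_sd >= 0,
              "noise_sd must be a non-negative number")
  shifts <- c(0, pi / 2, pi, 3 * pi / 2)
  frames <- lapply(shifts, function(s) {
    model$u0_intensity *
      (1 + model$beta^2 + 2 * model$beta * cos(model$delta_phi + s))
  })
  if (poisson || noise_sd > 0) {
    frames <- with_local_seed(seed, {
      lapply(frames, function(f) {
        if (poisson) {
          matrix(stats::rpois(length(f), pmax(f, 0)), nrow(f), ncol(f))
        } else {
          pmax(f + matrix(stats::rnorm(length(f), 0, noise_sd), nrow(f), ncol(f)), 0)
        }
      })
    })
  }
  frame_stack(frames)
}

#' Four-frame intensity stack
#'
#' @param frames list of exactly four numeric matrices of identical shape,
#'   ordered by modulator shift 0, pi/2, pi, 3*pi/2.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames) {
  assert_that(is.list(frames) && length(frames) == 4L,
              "a frame stack holds exactly 4 frames", format_error)
  shp <- dim(frames[[1L]])
  for (f in frames) {
    assert_that(is.matrix(f) && is.numeric(f) && all(dim(f) == shp),
                "frames must be numeric matrices of identical shape", format_error)
  }
  structure(list(frames = frames, shifts = c(0, pi / 2, pi, 3 * pi / 2)),
            class = "frame_stack")
}

#' Retrieve the quantitative phase from four phase-shifted frames
#'
#' Inverts the four-step phase-shifting algebra: the cross-term phase comes
#' from `atan2(I3 - I1, I0 - I2)`, the modulation envelope and the frame mean
#' determine `|U0|^2` and `beta`, and the specimen phase follows as
#' `atan2(beta*sin(dphi), 1 + beta*cos(dphi))`. Pixels whose modulation
#' envelope falls below `modulation_floor` times the frame mean carry no
#' usable interference signal; they are flagged and assigned phase 0.
#'
#' @param frames a [frame_stack()].
#' @param modulation_floor relative envelope threshold below which a pixel is
#'   flagged as unmodulated (default `1e-12`).
#' @param pixel_size pixel pitch passed through to the output [phase_map()].
#' @return list with `phase` (a [phase_map()]), `beta` (matrix of recovered
#'   amplitude ratios), `delta_phi` (matrix), and `low_modulation` (logical
#'   matrix flagging unusable pixels).
#' @export
retrieve_phase <- function(frames, modulation_floor = 1e-12, pixel_size = 0.5) {
  if (is.list(frames) && !inherits(frames, "frame_stack")) frames <- frame_stack(frames)
  assert_that(inherits(frames, "frame_stack"), "frames must be a frame_stack",
              format_error)
  I0 <- frames$frames[[1L]]; I1 <- frames$frames[[2L]]
  I2 <- frames$frames[[3L]]; I3 <- frames$frames[[4L]]
  dcos <- I0 - I2                       # 4|U0|^2 beta cos(dphi)
  dsin <- I3 - I1                       # 4|U0|^2 beta sin(dphi)
  G <- sqrt(dcos^2 + dsin^2)            # 4|U0|^2 beta
  S <- (I0 + I1 + I2 + I3) / 4          # |U0|^2 (1 + beta^2)
  low <- G < modulation_floor * pmax(S, .Machine$double.xmin)
  delta_phi <- atan2(dsin, dcos)
  disc <- pmax(S^2 - G^2 / 4, 0)        # (|U0|^2 (1 - beta^2))^2
  root <- sqrt(disc)
  larger <- (S + root) / 2              # |U0|^2: unscattered light dominates
  smaller <- pmax((S - root) / 2, 0)    # |U1|^2
  beta <- sqrt(smaller / pmax(larger, .Machine$double.xmin))
  phi <- atan2(beta * sin(delta_phi), 1 + beta * cos(delta_phi))
  phi[low] <- 0
  delta_phi[low] <- 0
  beta[low] <- 0
  list(phase = phase_map(phi, pixel_size = pixel_size),
       beta = beta, delta_phi = delta_phi, low_modulation = low)
}

#' Stitch a grid of mosaic tiles into one phase map
#'
#' Tiles are placed at known offsets (no registration) on a grid with a fixed
#' per-axis overlap; overlapping regions are blended by linear feathering
#' (per-tile weights ramp linearly over the overlap zone and are normalized,
#' so wherever all contributing tiles agree the output equals the common
#' value exactly).
#'
#' @param tiles list of tiles ([phase_map()] or numeric matrix), in row-major
#'   grid order.
#' @param layout integer vector `(tile_rows, tile_cols)` of the grid.
#' @param overlap overlap between adjacent tiles, pixels (same both axes).
#' @return a [phase_map()] of the assembled mosaic.
#' @export
stitch_tiles <- function(tiles, layout, overlap = 0) {
  assert_that(length(layout) == 2L && all(layout >= 1L), "layout must be (rows, cols)")
  assert_that(is.list(tiles), "tiles must be a list", format_error)
  assert_that(length(tiles) == prod(layout),
              sprintf("ragged grid: %d tiles for a %d x %d layout",
                      length(tiles), layout[1L], layout[2L]), format_error)
  mats <- lapply(tiles, as_phase_matrix)
  shp <- dim(mats[[1L]])
  for (m in mats) assert_that(all(dim(m) == shp), "all tiles must share one shape",
                              format_error)
  assert_that(is_scalar_number(overlap) && overlap >= 0 && overlap < min(shp),
              "overlap must be non-negative and smaller than the tile side")
  overlap <- as.integer(overlap)
  px <- if (inherits(tiles[[1L]], "phase_map")) tiles[[1L]]$pixel_size else 0.5
  step <- shp - overlap
  out_shape <- layout * step + overlap
  ramp <- function(n) pmin(pmin(seq_len(n), n - seq_len(n) + 1L), overlap + 1L) /
    (overlap + 1L)
  w_tile <- outer(ramp(shp[1L]), ramp(shp[2L]))
  acc <- matrix(0, out_shape[1L], out_shape[2L])
  wacc <- matrix(0, out_shape[1L], out_shape[2L])
  for (i in seq_len(layout[1L])) {
    for (j in seq_len(layout[2L])) {
      m <- mats[[(i - 1L) * layout[2L] + j]]
      rr <- (i - 1L) * step[1L] + seq_len(shp[1L])
      cc <- (j - 1L) * step[2L] + seq_len(shp[2L])
      acc[rr, cc] <- acc[rr, cc] + w_tile * m
      wacc[rr, cc] <- wacc[rr, cc] + w_tile
    }
  }
  phase_map(acc / wacc, pixel_size = px, unwrapped = TRUE)
}

#' Cut a phase map into a grid of overlapping tiles
#'
#' Inverse of [stitch_tiles()] for maps whose size matches the grid
#' arithmetic `layout * (tile - overlap) + overlap`.
#'
#' @param map a [phase_map()] or numeric matrix.
#' @param layout integer vector `(tile_rows, tile_cols)`.
#' @param overlap overlap in pixels.
#' @return list of [phase_map()] tiles in row-major order.
#' @export
split_tiles <- function(map, layout, overlap = 0) {
  m <- as_phase_matrix(map)
  overlap <- as.integer(overlap)
  shp <- dim(m)
  tile <- (shp - overlap) / layout + overlap
  assert_that(all(tile == round(tile)),
              "map size incompatible with layout/overlap", format_error)
  tile <- as.integer(tile)
  step <- tile - overlap
  px <- if (inherits(map, "phase_map")) map$pixel_size else 0.5
  out <- vector("list", prod(layout))
  for (i in seq_len(layout[1L])) {
    for (j in seq_len(layout[2L])) {
      rr <- (i - 1L) * step[1L] + seq_len(tile[1L])
      cc <- (j - 1L) * step[2L] + seq_len(tile[2L])
      out[[(i - 1L) * layout[2L] + j]] <- phase_map(m[rr, cc], pixel_size = px,
                                                    unwrapped = TRUE)
    }
  }
  out
}
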