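# Gland instance detection: anchor generation, augmentation policy, the
# deterministic classical segmenter, threshold filtering and NMS.

#' Detector configuration
#'
#' Defaults follow the reference two-stage detector setup: square anchor
#' scales (8, 16, 32, 64, 128) px with aspect ratios (0.5, 1, 2) — 15 anchor
#' boxes per anchor point — three classes (background, cancer, normal),
#' SGD with learning rate 0.001, momentum 0.9, weight decay 1e-4 and batch
#' size 1, and a two-phase schedule that first trains only the heads and
#' then all layers. `detection_confidence` is the score threshold below
#' which detections are discarded (0.70 / 0.80 / 0.90 are the standard
#' operating points; 0.90 the default).
#'
#' @param anchor_scales anchor box side lengths in pixels, ascending.
#' @param anchor_ratios aspect ratios height/width.
#' @param classes class set; first entry is the background class.
#' @param learning_rate,momentum,weight_decay,batch_size optimizer settings.
#' @param detection_confidence default score threshold, in (0, 1).
#' @param epochs_heads_only,epochs_all_layers two-phase schedule lengths.
#' @param hidden_units width of the trainable detector's hidden layer.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(anchor_scales = c(8, 16, 32, 64, 128),
                            anchor_ratios = c(0.5, 1, 2),
                            classes = c("background", "cancer", "normal"),
                            learning_rate = 0.001, momentum = 0.9,
                            weight_decay = 1e-4, batch_size = 1L,
                            detection_confidence = 0.9,
                            epochs_heads_only = 50L, epochs_all_layers = 350L,
                            hidden_units = 8L) {
  assert_that(all(anchor_scales > 0) && !is.unsorted(anchor_scales, strictly = TRUE),
              "anchor_scales must be positive and ascending")
  assert_that(all(anchor_ratios > 0), "anchor_ratios must be positive")
  assert_that(is_scalar_number(detection_confidence) &&
                detection_confidence > 0 && detection_confidence < 1,
              "detection_confidence must be in (0, 1)")
  assert_that(epochs_heads_only >= 0 && epochs_all_layers >= 0,
              "epoch counts must be non-negative")
  structure(list(anchor_scales = anchor_scales, anchor_ratios = anchor_ratios,
                 classes = classes, learning_rate = learning_rate,
                 momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 detection_confidence = detection_confidence,
                 epochs_heads_only = as.integer(epochs_heads_only),
                 epochs_all_layers = as.integer(epochs_all_layers),
                 hidden_units = as.integer(hidden_units)),
            class = "detector_config")
}

#' Generate region-proposal anchor boxes
#'
#' Places one anchor point per `feature_stride` x `feature_stride` cell
#' (at the cell center) and emits one box per (scale, ratio) pair: a box of
#' scale `s` and ratio `r` has height `s * sqrt(r)` and width `s / sqrt(r)`
#' (area `s^2`), centered on the point. Boxes extending beyond the image are
#' kept and flagged `clipped`.
#'
#' @param config a [detector_config()].
#' @param feature_stride anchor grid stride, pixels; must divide both image
#'   dimensions.
#' @param image_shape integer `(rows, cols)`.
#' @return data.frame with 0-based half-open box coordinates `r0, c0, r1,
#'   c1`, plus `scale`, `ratio`, and `clipped`.
#' @export
generate_anchors <- function(config, feature_stride, image_shape) {
  assert_that(inherits(config, "detector_config"), "config must be a detector_config")
  assert_that(all(image_shape %% feature_stride == 0),
              "feature_stride must divide the image dimensions")
  centers_r <- (seq_len(image_shape[1L] / feature_stride) - 0.5) * feature_stride
  centers_c <- (seq_len(image_shape[2L] / feature_stride) - 0.5) * feature_stride
  grid <- expand.grid(cy = centers_r, cx = centers_c,
                      scale = config$anchor_scales, ratio = config$anchor_ratios)
  h <- grid$scale * sqrt(grid$ratio)
  w <- grid$scale / sqrt(grid$ratio)
  out <- data.frame(r0 = grid$cy - h / 2, c0 = grid$cx - w / 2,
                    r1 = grid$cy + h / 2, c1 = grid$cx + w / 2,
                    scale = grid$scale, ratio = grid$ratio)
  out$clipped <- out$r0 < 0 | out$c0 < 0 |
    out$r1 > image_shape[1L] | out$c1 > image_shape[2L]
  out
}

#' Augmentation policy
#'
#' A moderate augmentation set: horizontal flip with probability 1/2,
#' vertical flip with probability 1/2, right-angle rotation drawn uniformly
#' from {none} + `rotations`, and Gaussian blur with sigma drawn uniformly
#' from `blur_sigma_range` (applied to the image only, never the masks).
#'
#' @param hflip_prob,vflip_prob flip probabilities in `[0, 1]`.
#' @param rotations allowed rotation angles, degrees (subset of 90/180/270).
#' @param blur_sigma_range numeric `(min, max)` blur sigma, non-negative.
#' @return an object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(hflip_prob = 0.5, vflip_prob = 0.5,
                                rotations = c(90, 180, 270),
                                blur_sigma_range = c(0, 5)) {
  assert_that(hflip_prob >= 0 && hflip_prob <= 1 && vflip_prob >= 0 && vflip_prob <= 1,
              "flip probabilities must be in [0, 1]")
  assert_that(all(rotations %in% c(90, 180, 270)),
              "rotations must be right angles (90/180/270)")
  assert_that(length(blur_sigma_range) == 2L && all(blur_sigma_range >= 0) &&
                blur_sigma_range[1L] <= blur_sigma_range[2L],
              "blur_sigma_range must be a non-negative (min, max)")
  structure(list(hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 rotations = rotations, blur_sigma_range = blur_sigma_range),
            class = "augmentation_policy")
}

rot90_mat <- function(m, times) {
  times <- times %% 4L
  for (i in seq_len(times)) m <- t(m)[nrow(t(m)):1, , drop = FALSE]
  m
}
hflip_mat <- function(m) m[, ncol(m):1, drop = FALSE]
vflip_mat <- function(m) m[nrow(m):1, , drop = FALSE]

#' Apply a sampled augmentation to an image and its masks
#'
#' The same geometric transform (flips + right-angle rotation) is applied to
#' the image and every mask; blur is applied to the image only. Identical
#' seeds reproduce the identical transform.
#'
#' @param image a [phase_map()] or numeric matrix.
#' @param masks list of logical matrices aligned with the image (may be
#'   empty).
#' @param policy an [augmentation_policy()].
#' @param seed integer seed.
#' @return list with transformed `image` (same type as input) and `masks`.
#' @export
augment <- function(image, masks = list(), policy = augmentation_policy(),
                    seed = NULL) {
  img <- as_phase_matrix(image)
  for (m in masks) {
    assert_that(all(dim(m) == dim(img)), "masks must align with the image",
                format_error)
  }
  with_local_seed(seed, {
    do_h <- stats::runif(1L) < policy$hflip_prob
    do_v <- stats::runif(1L) < policy$vflip_prob
    rot_choices <- c(0, policy$rotations)
    rot <- if (length(rot_choices) > 1L) sample(rot_choices, 1L) else 0
    sigma <- stats::runif(1L, policy$blur_sigma_range[1L], policy$blur_sigma_range[2L])
    geom <- function(m) {
      if (do_h) m <- hflip_mat(m)
      if (do_v) m <- vflip_mat(m)
      if (rot > 0) m <- rot90_mat(m, rot / 90)
      m
    }
    img2 <- geom(img)
    if (sigma > 1e-8) img2 <- EBImage::gblur(img2, sigma = sigma)
    out_img <- if (inherits(image, "phase_map")) {
      phase_map(pmin(pmax(img2, -pi + 1e-9), pi), pixel_size = image$pixel_size,
                unwrapped = image$unwrapped)
    } else img2
    list(image = out_img, masks = lapply(masks, geom))
  })
}

#' Classical segmentation parameters
#'
#' The morphological scales (`smooth_sigma`, `closing_radius`,
#' `watershed_tolerance`) default to `NULL`, which resolves them at
#' segmentation time in proportion to the image side (values 2.5 / 7 / 10
#' at the reference 512 px scale), so one parameter set serves cores
#' rendered at any size.
#'
#' @param smooth_sigma Gaussian smoothing sigma before thresholding, px;
#'   `NULL` for `side/205`.
#' @param phase_threshold epithelial phase threshold, radians; `NULL` picks
#'   Otsu's threshold.
#' @param closing_radius disc radius for morphological closing, px; `NULL`
#'   for `side/73`.
#' @param min_area minimum filled instance area, as a fraction of the image
#'   area (scale-free).
#' @param watershed_tolerance minimum object-separating depth in the
#'   distance map; `NULL` for `side/51`.
#' @param roughness_cutoff circularity above which an instance is called
#'   cancer (a digitized disk scores ~1.1).
#' @param score_slope logistic slope converting the roughness margin into a
#'   confidence score.
#' @param min_contrast minimum epithelium-to-stroma phase contrast, radians;
#'   below it the tissue is treated as gland-free stroma (epithelial rings
#'   sit well above stroma, texture alone does not).
#' @param tissue_floor phase above which a pixel counts as tissue, radians;
#'   the near-zero mounting-medium background is excluded from
#'   thresholding.
#' @return an object of class `classical_params`.
#' @export
classical_params <- function(smooth_sigma = NULL, phase_threshold = NULL,
                             closing_radius = NULL, min_area = 0.002,
                             watershed_tolerance = NULL,
                             roughness_cutoff = 1.35, score_slope = 10,
                             min_contrast = 0.3, tissue_floor = 0.1) {
  structure(list(smooth_sigma = smooth_sigma, phase_threshold = phase_threshold,
                 closing_radius = closing_radius, min_area = min_area,
                 watershed_tolerance = watershed_tolerance,
                 roughness_cutoff = roughness_cutoff, score_slope = score_slope,
                 min_contrast = min_contrast, tissue_floor = tissue_floor),
            class = "classical_params")
}

# Resolve NULL morphological scales relative to the image side.
resolve_classical_params <- function(params, shape) {
  side <- min(shape)
  params$smooth_sigma <- params$smooth_sigma %||% max(side / 205, 1)
  params$closing_radius <- as.integer(params$closing_radius %||%
                                        max(round(side / 73), 2L))
  params$watershed_tolerance <- params$watershed_tolerance %||% max(side / 51, 2)
  params
}

#' Deterministic morphological gland segmenter
#'
#' Reference detector requiring no training: Gaussian smoothing, epithelial-
#' phase thresholding (Otsu by default), morphological closing, hole
#' filling, watershed splitting of fused glands on the distance map, and a
#' size filter. Each instance keeps the thresholded ring pixels inside its
#' watershed region as its mask, and is classified by the boundary-roughness
#' statistic ([roughness_statistic()]): above `roughness_cutoff` means
#' cancer. Scores are the logistic-normalized margin from the cutoff, so
#' confidently smooth or confidently rough glands score near 1. The whole
#' pipeline is deterministic.
#'
#' @param core a [phase_map()] or numeric matrix.
#' @param params a [classical_params()].
#' @return list of [gland_instance()] sorted by descending score.
#' @export
classical_segment <- function(core, params = classical_params()) {
  img <- as_phase_matrix(core)
  assert_that(all(is.finite(img)), "core must be finite", format_error)
  nr <- nrow(img); nc <- ncol(img)
  params <- resolve_classical_params(params, c(nr, nc))
  sm <- EBImage::gblur(img, sigma = params$smooth_sigma)
  # threshold within tissue only: the near-zero mounting-medium background
  # outside the core footprint must not drive the epithelium/stroma split
  tissue <- sm > params$tissue_floor
  if (sum(tissue) < 0.01 * nr * nc) return(list())
  thr <- params$phase_threshold
  if (is.null(thr)) {
    vals <- sm[tissue]
    rng <- range(vals)
    if (diff(rng) < 1e-9) return(list())
    u <- (vals - rng[1L]) / diff(rng)
    thr <- rng[1L] + diff(rng) *
      EBImage::otsu(EBImage::Image(matrix(u, ncol = 1L)), range = c(0, 1))
  }
  bw <- sm > thr
  if (!any(bw) || all(bw)) return(list())
  fg <- bw & tissue; bg <- tissue & !bw
  if (!any(fg) || !any(bg)) return(list())
  if (mean(sm[fg]) - mean(sm[bg]) < params$min_contrast) return(list())
  brush <- EBImage::makeBrush(2L * params$closing_radius + 1L, shape = "disc")
  bw <- EBImage::closing(bw, brush) > 0
  filled <- EBImage::fillHull(matrix(as.integer(bw), nr, nc))
  dm <- EBImage::distmap(filled)
  seg <- EBImage::watershed(dm, tolerance = params$watershed_tolerance, ext = 1L)
  seg <- matrix(as.integer(seg), nr, nc)
  min_px <- params$min_area * nr * nc
  out <- list()
  for (k in seq_len(max(seg))) {
    region <- seg == k
    if (sum(region) < min_px) next
    ring <- region & bw
    if (!any(ring)) next
    rough <- roughness_statistic(region)
    if (!is.finite(rough)) next
    lab <- if (rough > params$roughness_cutoff) "cancer" else "normal"
    score <- 1 / (1 + exp(-params$score_slope * abs(rough - params$roughness_cutoff)))
    out[[length(out) + 1L]] <- gland_instance(ring, lab, score = score)
  }
  out[order(vapply(out, `[[`, numeric(1L), "score"), decreasing = TRUE)]
}

# Box IoU on half-open (r0, c0, r1, c1).
box_iou <- function(a, b) {
  ih <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  iw <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- ih * iw
  area <- function(x) (x[3L] - x[1L]) * (x[4L] - x[2L])
  if (inter <= 0) return(0)
  inter / (area(a) + area(b) - inter)
}

#' Non-maximum suppression over instances
#'
#' Greedy by descending score; an instance is suppressed when its bounding-
#' box IoU with an already kept instance reaches `iou`.
#'
#' @param instances list of [gland_instance()].
#' @param iou suppression threshold (default 0.3).
#' @return filtered list, sorted by descending score.
#' @export
nms_instances <- function(instances, iou = 0.3) {
  if (length(instances) <= 1L) return(instances)
  ord <- order(vapply(instances, `[[`, numeric(1L), "score"), decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    cand <- instances[[i]]
    drop <- any(vapply(kept, function(k) box_iou(k$bbox, cand$bbox) >= iou,
                       logical(1L)))
    if (!drop) kept[[length(kept) + 1L]] <- cand
  }
  kept
}

#' Detect gland instances in a core
#'
#' Dispatches on the model: [classical_params()] runs the deterministic
#' segmenter, a trained `slim_detector` runs the two-stage detector, and an
#' [oracle_detector()] echoes its ground truth. Only instances with
#' `score >= detection_confidence` are returned, sorted by descending score,
#' so the detections at a higher threshold are always a prefix of those at a
#' lower one.
#'
#' @param core a [phase_map()] or numeric matrix.
#' @param model detector state (see above).
#' @param detection_confidence score threshold in (0, 1].
#' @return list of [gland_instance()].
#' @export
detect <- function(core, model, detection_confidence = 0.9) {
  assert_that(is_scalar_number(detection_confidence) &&
                detection_confidence > 0 && detection_confidence <= 1,
              "detection_confidence must be in (0, 1]")
  insts <- if (inherits(model, "classical_params")) {
    classical_segment(core, model)
  } else if (inherits(model, "slim_detector")) {
    detect_nn(core, model)
  } else if (inherits(model, "oracle_detector")) {
    lapply(model$truth$instances, function(x) {
      gland_instance(x$mask, x$class_label, score = 1, polygon = x$polygon)
    })
  } else {
    parameter_error("model must be classical_params, slim_detector or oracle_detector")
  }
  insts <- insts[vapply(insts, `[[`, numeric(1L), "score") >= detection_confidence]
  insts[order(vapply(insts, `[[`, numeric(1L), "score"), decreasing = TRUE)]
}

#' Oracle detector: echoes ground truth with score 1
#'
#' @param truth a [core_ground_truth()].
#' @return an object of class `oracle_detector` usable with [detect()].
#' @export
oracle_detector <- function(truth) {
  assert_that(inherits(truth, "core_ground_truth"), "truth must be a core_ground_truth")
  structure(list(truth = truth), class = "oracle_detector")
}
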