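# Trainable two-stage gland detector.
#
# Stage 1 proposes candidate regions by running the morphological proposal
# machinery at several permissive thresholds (high recall, low precision).
# Stage 2 scores each candidate with a small multilayer perceptron over
# rotation/flip-invariant region descriptors and a 3-way softmax
# (background / cancer / normal). The head is trained by SGD with momentum
# and weight decay at batch size 1; the two-phase schedule first trains only
# the softmax head on a frozen hidden layer, then unfreezes all layers.
# Candidates are labeled against ground truth by mask IoU: >= 0.5 adopts the
# matched gland's class, < 0.1 becomes background, the band between is
# excluded from the loss (the usual proposal-assignment rule).

#' Propose candidate gland regions
#'
#' Runs the smoothing/threshold/closing/watershed chain at several threshold
#' offsets around Otsu's value and pools the resulting regions, de-duplicated
#' by bounding-box IoU (> 0.7 keeps the first). Deliberately permissive:
#' recall matters here, precision is the classifier's job.
#'
#' @param core a [phase_map()] or numeric matrix.
#' @param offsets multiplicative threshold offsets around the Otsu value.
#' @return list of [gland_instance()] with placeholder labels and score 1.
#' @export
propose_regions <- function(core, offsets = c(0.85, 1, 1.15)) {
  img <- as_phase_matrix(core)
  rng <- range(EBImage::gblur(img, sigma = 2.5))
  if (diff(rng) < 1e-9) return(list())
  u <- (EBImage::gblur(img, sigma = 2.5) - rng[1L]) / diff(rng)
  base_thr <- rng[1L] + diff(rng) *
    EBImage::otsu(EBImage::Image(u), range = c(0, 1))
  pool <- list()
  for (off in offsets) {
    insts <- classical_segment(img, classical_params(phase_threshold = base_thr * off))
    for (inst in insts) {
      dup <- any(vapply(pool, function(p) box_iou(p$bbox, inst$bbox) > 0.7,
                        logical(1L)))
      if (!dup) pool[[length(pool) + 1L]] <- inst
    }
  }
  pool
}

# Rotation/flip-invariant descriptors of one candidate region.
region_features <- function(img, inst) {
  m <- inst$mask
  filled <- EBImage::fillHull(matrix(as.integer(m), nrow(m), ncol(m)))
  area <- sum(m); farea <- sum(filled)
  vals <- img[m]
  mom <- EBImage::computeFeatures.moment(filled)
  shp <- EBImage::computeFeatures.shape(filled)
  gr <- range(img)
  c(log_area = log(farea),
    roughness = roughness_statistic(m),
    lumen_frac = 1 - area / farea,
    mean_phase = mean(vals),
    sd_phase = stats::sd(vals),
    eccentricity = mom[1L, "m.eccentricity"],
    radius_cv = shp[1L, "s.radius.sd"] / max(shp[1L, "s.radius.mean"], 1e-6),
    rel_phase = (mean(vals) - mean(img)) / max(diff(gr), 1e-6))
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

nn_init <- function(n_in, hidden, n_out, seed) {
  with_local_seed(seed, list(
    W1 = matrix(stats::rnorm(hidden * n_in, 0, 0.3), hidden, n_in),
    b1 = rep(0, hidden),
    W2 = matrix(stats::rnorm(n_out * hidden, 0, 0.3), n_out, hidden),
    b2 = rep(0, n_out)))
}

nn_forward <- function(w, x) {
  h <- tanh(w$W1 %*% x + w$b1)
  list(h = h, p = softmax(drop(w$W2 %*% h + w$b2)))
}

# One SGD step on example (x, y); returns updated weights + velocity.
nn_step <- function(w, v, x, y, lr, momentum, decay, heads_only) {
  fw <- nn_forward(w, x)
  dz2 <- fw$p; dz2[y] <- dz2[y] - 1                     # softmax cross-entropy
  gW2 <- dz2 %o% drop(fw$h); gb2 <- dz2
  grads <- list(W2 = gW2 + decay * w$W2, b2 = gb2)
  if (!heads_only) {
    dh <- drop(t(w$W2) %*% dz2) * (1 - drop(fw$h)^2)
    grads$W1 <- dh %o% x + decay * w$W1
    grads$b1 <- dh
  }
  for (nm in names(grads)) {
    v[[nm]] <- momentum * v[[nm]] - lr * grads[[nm]]
    w[[nm]] <- w[[nm]] + v[[nm]]
  }
  list(w = w, v = v, loss = -log(max(fw$p[y], 1e-12)))
}

nn_loss <- function(w, X, y) {
  if (!nrow(X)) return(NA_real_)
  mean(vapply(seq_len(nrow(X)), function(i)
    -log(max(nn_forward(w, X[i, ])$p[y[i]], 1e-12)), numeric(1L)))
}

# Build (features, labels) training examples from one core.
candidate_examples <- function(img, truth, cfg) {
  props <- propose_regions(img)
  if (!length(props)) return(NULL)
  X <- t(vapply(props, function(p) region_features(img, p),
                numeric(length(feature_names()))))
  y <- integer(nrow(X))
  for (i in seq_along(props)) {
    ious <- vapply(truth$instances, function(t)
      mask_iou(props[[i]]$mask, t$mask), numeric(1L))
    if (length(ious) && max(ious) >= 0.5) {
      y[i] <- match(truth$instances[[which.max(ious)]]$class_label, cfg$classes)
    } else if (!length(ious) || max(ious) < 0.1) {
      y[i] <- 1L  # background
    } else {
      y[i] <- NA_integer_  # ambiguous; excluded from the loss
    }
  }
  keep <- !is.na(y)
  list(X = X[keep, , drop = FALSE], y = y[keep])
}

feature_names <- function() {
  c("log_area", "roughness", "lumen_frac", "mean_phase", "sd_phase",
    "eccentricity", "radius_cv", "rel_phase")
}

#' Train the two-stage gland detector
#'
#' Builds candidate examples from the training cores (each core contributes
#' its original image plus `n_augment` seeded augmented variants), then runs
#' the two-phase SGD schedule: `epochs_heads_only` epochs updating only the
#' softmax head, followed by `epochs_all_layers` epochs updating all layers.
#' Per-epoch validation loss is logged and a weight checkpoint is kept per
#' epoch so later epochs can be compared. Training never touches cores
#' assigned to the test split.
#'
#' @param dataset a `tma_dataset` (materialized cores are used when present,
#'   otherwise cores are rendered on the fly).
#' @param config a [detector_config()].
#' @param policy an [augmentation_policy()].
#' @param seed integer seed for initialization, augmentation and shuffling.
#' @param n_augment augmented variants per training core.
#' @param checkpoint_dir optional directory; per-epoch checkpoints are saved
#'   as RDS files when given.
#' @return an object of class `slim_detector` with `weights`, `feature_mean`
#'   / `feature_sd` (normalization layer), `history` (per-epoch data.frame),
#'   and `checkpoints` (list of per-epoch weights).
#' @export
train_detector <- function(dataset, config = detector_config(),
                           policy = augmentation_policy(), seed = NULL,
                           n_augment = 1L, checkpoint_dir = NULL) {
  man <- dataset$manifest
  train_ids <- man$core_id[man$split == "train"]
  val_ids <- man$core_id[man$split == "validation"]
  assert_that(length(train_ids) > 0L, "training set is empty")

  get_core <- function(id) {
    if (!is.null(dataset$cores)) dataset$cores[[id]] else materialize_core(dataset, id)
  }
  collect <- function(ids, augmented) {
    Xs <- list(); ys <- list()
    for (i in seq_along(ids)) {
      core <- get_core(ids[i])
      variants <- list(as_phase_matrix(core$phase))
      truths <- list(core$truth)
      if (augmented && n_augment > 0L) {
        for (a in seq_len(n_augment)) {
          masks <- lapply(core$truth$instances, `[[`, "mask")
          aug <- augment(core$phase, masks, policy,
                         seed = derive_seed(seed %||% 0L, i * 131L + a))
          insts <- lapply(seq_along(masks), function(k)
            gland_instance(aug$masks[[k]],
                           core$truth$instances[[k]]$class_label))
          variants[[length(variants) + 1L]] <- as_phase_matrix(aug$image)
          truths[[length(truths) + 1L]] <-
            core_ground_truth(insts, core$truth$core_label,
                              core$truth$core_id, dim(variants[[1L]]))
        }
      }
      for (v in seq_along(variants)) {
        ex <- candidate_examples(variants[[v]], truths[[v]], config)
        if (!is.null(ex) && nrow(ex$X)) {
          Xs[[length(Xs) + 1L]] <- ex$X
          ys[[length(ys) + 1L]] <- ex$y
        }
      }
    }
    list(X = do.call(rbind, Xs), y = unlist(ys))
  }

  tr <- collect(train_ids, augmented = TRUE)
  assert_that(!is.null(tr$X) && nrow(tr$X) > 0L,
              "no candidate regions found in the training cores")
  va <- if (length(val_ids)) collect(val_ids, augmented = FALSE) else NULL

  mu <- colMeans(tr$X)
  sd_ <- pmax(apply(tr$X, 2L, stats::sd), 1e-6)
  Xtr <- sweep(sweep(tr$X, 2L, mu), 2L, sd_, "/")
  Xva <- if (!is.null(va) && !is.null(va$X)) sweep(sweep(va$X, 2L, mu), 2L, sd_, "/")
  else NULL

  n_out <- length(config$classes)
  w <- nn_init(ncol(Xtr), config$hidden_units, n_out, seed = derive_seed(seed %||% 0L, 7L))
  v <- lapply(w, function(p) p * 0)
  total_epochs <- config$epochs_heads_only + config$epochs_all_layers
  history <- data.frame(epoch = integer(0), phase = character(0),
                        train_loss = numeric(0), val_loss = numeric(0))
  checkpoints <- vector("list", total_epochs)
  for (ep in seq_len(total_epochs)) {
    heads_only <- ep <= config$epochs_heads_only
    ord <- with_local_seed(derive_seed(seed %||% 0L, 1000L + ep),
                           sample(nrow(Xtr)))
    losses <- numeric(length(ord))
    for (ii in seq_along(ord)) {
      i <- ord[ii]
      st <- nn_step(w, v, Xtr[i, ], tr$y[i], config$learning_rate,
                    config$momentum, config$weight_decay, heads_only)
      w <- st$w; v <- st$v; losses[ii] <- st$loss
    }
    vl <- if (!is.null(Xva)) nn_loss(w, Xva, va$y) else NA_real_
    history <- rbind(history, data.frame(
      epoch = ep, phase = if (heads_only) "heads" else "all",
      train_loss = mean(losses), val_loss = vl))
    checkpoints[[ep]] <- w
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(w, file.path(checkpoint_dir, sprintf("epoch_%04d.rds", ep)))
    }
  }
  structure(list(weights = w, feature_mean = mu, feature_sd = sd_,
                 config = config, history = history, checkpoints = checkpoints),
            class = "slim_detector")
}

#' Untrained detector (random initialization)
#'
#' The same two-stage detector with freshly initialized weights and an
#' identity normalization layer; the baseline against which training gains
#' are measured.
#'
#' @param config a [detector_config()].
#' @param seed integer seed for the initialization.
#' @param n_features number of region descriptors.
#' @return an object of class `slim_detector`.
#' @export
untrained_detector <- function(config = detector_config(), seed = NULL,
                               n_features = length(feature_names())) {
  w <- nn_init(n_features, config$hidden_units, length(config$classes),
               seed = seed)
  structure(list(weights = w, feature_mean = rep(0, n_features),
                 feature_sd = rep(1, n_features), config = config,
                 history = NULL, checkpoints = list(w)),
            class = "slim_detector")
}

#' Restore a detector at an earlier training epoch
#'
#' @param model a trained `slim_detector`.
#' @param epoch epoch number (1-based) whose checkpoint to load.
#' @return a `slim_detector` with that epoch's weights.
#' @export
detector_at_epoch <- function(model, epoch) {
  assert_that(epoch >= 1L && epoch <= length(model$checkpoints),
              "epoch outside the trained range")
  model$weights <- model$checkpoints[[epoch]]
  model
}

# Stage-2 inference used by detect() for slim_detector models.
detect_nn <- function(core, model) {
  img <- as_phase_matrix(core)
  props <- propose_regions(img)
  if (!length(props)) return(list())
  out <- list()
  for (p in props) {
    x <- (region_features(img, p) - model$feature_mean) / model$feature_sd
    prob <- nn_forward(model$weights, x)$p
    k <- which.max(prob)
    cls <- model$config$classes[k]
    if (cls == "background") next
    out[[length(out) + 1L]] <- gland_instance(p$mask, cls, score = prob[k])
  }
  nms_instances(out, iou = 0.3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
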