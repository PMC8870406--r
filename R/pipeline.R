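# End-to-end orchestration: reproducible run configuration and the
# simulate / train / infer / evaluate stages, all driven by one top-level
# seed. Every stage writes into a run directory holding the serialized
# config, a log, and versioned outputs sufficient to re-derive reports
# without re-running detection.

#' Run configuration
#'
#' All tunables of a pipeline run. The configuration is serialized verbatim
#' into every run directory; reloading it reproduces deterministic stages
#' byte-identically.
#'
#' @param seed top-level integer seed; all randomness flows from it.
#' @param out_dir run directory.
#' @param synthetic list of [generate_dataset()] arguments: `n_cancer`,
#'   `n_normal`, `fractions`, `allocation`, `shape`.
#' @param detector a [detector_config()].
#' @param augmentation an [augmentation_policy()].
#' @param diagnosis_threshold core-diagnosis threshold (default 0.90).
#' @param iou_min evaluation match criterion (default 0.5).
#' @param confidence_thresholds sweep thresholds (default 0.70/0.80/0.90).
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("slimscreen_run_"),
                       synthetic = list(n_cancer = 6L, n_normal = 6L,
                                        fractions = c(0.76, 0.12, 0.12),
                                        allocation = "balanced",
                                        shape = c(256L, 256L)),
                       detector = detector_config(),
                       augmentation = augmentation_policy(),
                       diagnosis_threshold = 0.90, iou_min = 0.5,
                       confidence_thresholds = c(0.70, 0.80, 0.90)) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 synthetic = synthetic, detector = detector,
                 augmentation = augmentation,
                 diagnosis_threshold = diagnosis_threshold, iou_min = iou_min,
                 confidence_thresholds = confidence_thresholds),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or a [run_config()] (read).
#' @export
write_run_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "list")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(seed = raw$seed, out_dir = raw$out_dir,
                    synthetic = raw$synthetic,
                    detector = do.call(detector_config, raw$detector),
                    augmentation = do.call(augmentation_policy, raw$augmentation),
                    diagnosis_threshold = raw$diagnosis_threshold,
                    iou_min = raw$iou_min,
                    confidence_thresholds = unlist(raw$confidence_thresholds))
  cfg$synthetic$fractions <- unlist(cfg$synthetic$fractions)
  cfg$synthetic$shape <- unlist(cfg$synthetic$shape)
  cfg
}

log_line <- function(run_dir, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...))
  cat(line, "\n", file = file.path(run_dir, "log.txt"), append = TRUE, sep = "")
  invisible(line)
}

#' Simulate a dataset to disk
#'
#' Generates the synthetic dataset of `config$synthetic`, renders every
#' core, and writes phase-map TIFFs, instance label TIFFs, VIA-dialect
#' polygon annotations, a JSON manifest (core ids, file paths, split
#' assignment, core labels) and the serialized config. The manifest content
#' is fully determined by the config, so re-running with the same seed
#' reproduces it byte-identically.
#'
#' @param config a [run_config()].
#' @return the run directory path, invisibly.
#' @export
cmd_simulate <- function(config) {
  run_dir <- config$out_dir
  dir.create(file.path(run_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(run_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(run_dir, "config.yaml"))
  syn <- config$synthetic
  ds <- generate_dataset(syn$n_cancer, syn$n_normal, fractions = syn$fractions,
                         seed = config$seed,
                         allocation = syn$allocation %||% "balanced",
                         shape = syn$shape)
  log_line(run_dir, "simulate: %d cores (%d cancer / %d normal)",
           nrow(ds$manifest), syn$n_cancer, syn$n_normal)
  truths <- list()
  entries <- list()
  for (i in seq_len(nrow(ds$manifest))) {
    row <- ds$manifest[i, ]
    core <- materialize_core(ds, row$core_id)
    img_rel <- file.path("images", paste0(row$core_id, ".tif"))
    msk_rel <- file.path("masks", paste0(row$core_id, "_labels.tif"))
    write_phase_tiff(core$phase, file.path(run_dir, img_rel))
    write_label_tiff(label_image(core$truth), file.path(run_dir, msk_rel))
    truths[[length(truths) + 1L]] <- core$truth
    entries[[length(entries) + 1L]] <- list(
      core_id = row$core_id, class_label = row$class_label, split = row$split,
      seed = row$seed, image = img_rel, mask = msk_rel,
      n_glands = length(core$truth$instances))
  }
  write_via_json(truths, file.path(run_dir, "annotations_via.json"))
  jsonlite::write_json(
    list(cores = entries, fractions = syn$fractions,
         shape = syn$shape, allocation = syn$allocation %||% "balanced",
         seed = config$seed),
    file.path(run_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  log_line(run_dir, "simulate: wrote manifest for %d cores", length(entries))
  invisible(run_dir)
}

#' Load a simulated run back from disk
#'
#' @param run_dir directory written by [cmd_simulate()].
#' @return a `tma_dataset` whose `$cores` are loaded from the stored TIFFs
#'   and VIA annotations.
#' @export
load_run_dataset <- function(run_dir) {
  mf <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
  via <- read_via_json(file.path(run_dir, "annotations_via.json"))
  shape <- as.integer(unlist(mf$shape))
  rows <- lapply(mf$cores, function(e)
    data.frame(core_id = e$core_id, class_label = e$class_label,
               split = e$split, seed = as.integer(e$seed),
               stringsAsFactors = FALSE))
  manifest <- do.call(rbind, rows)
  cores <- lapply(mf$cores, function(e) {
    phase <- read_phase_tiff(file.path(run_dir, e$image))
    labs <- read_label_tiff(file.path(run_dir, e$mask))
    entry <- via[[basename(e$image)]]
    classes <- vapply(entry$regions, `[[`, character(1L), "class_label")
    insts <- lapply(seq_along(entry$regions), function(k)
      gland_instance(labs == k, classes[k], score = 1,
                     polygon = entry$regions[[k]]$polygon))
    list(phase = phase,
         truth = core_ground_truth(insts, e$class_label, e$core_id, shape))
  })
  names(cores) <- manifest$core_id
  structure(list(manifest = manifest,
                 splits = split(manifest$core_id, manifest$split),
                 fractions = unlist(mf$fractions), shape = shape,
                 allocation = mf$allocation, cores = cores),
            class = "tma_dataset")
}

#' Train the detector on a simulated run
#'
#' Trains on the train split with the validation split for per-epoch loss;
#' test cores are never read. Checkpoints and the training history are
#' written under `<run_dir>/model/`.
#'
#' @param config a [run_config()].
#' @param run_dir directory written by [cmd_simulate()] (defaults to
#'   `config$out_dir`).
#' @return the trained `slim_detector`, invisibly.
#' @export
cmd_train <- function(config, run_dir = config$out_dir) {
  ds <- load_run_dataset(run_dir)
  ds$cores[ds$manifest$core_id[ds$manifest$split == "test"]] <- NULL
  model_dir <- file.path(run_dir, "model")
  model <- train_detector(ds, config = config$detector,
                          policy = config$augmentation,
                          seed = derive_seed(config$seed, 17L),
                          checkpoint_dir = file.path(model_dir, "checkpoints"))
  utils::write.csv(model$history, file.path(model_dir, "history.csv"),
                   row.names = FALSE)
  saveRDS(model, file.path(model_dir, "model.rds"))
  log_line(run_dir, "train: %d epochs, final val loss %.4f",
           nrow(model$history), utils::tail(model$history$val_loss, 1L))
  invisible(model)
}

detections_json_path <- function(run_dir, core_id) {
  file.path(run_dir, "detections", paste0(core_id, ".json"))
}

#' Run detection and core diagnosis over a split
#'
#' Detects gland instances on every core of `split` with the chosen
#' detector, writes per-core detection JSON (polygonized masks, boxes,
#' labels, scores) plus detection label TIFFs, and aggregates gland calls
#' into core diagnoses (CSV + JSON).
#'
#' @param config a [run_config()].
#' @param run_dir simulated run directory.
#' @param detector `"classical"`, `"cnn"` or `"oracle"`.
#' @param split which split to process (default `"test"`).
#' @param model a trained `slim_detector` for `detector = "cnn"`; defaults
#'   to `<run_dir>/model/model.rds`.
#' @param detection_confidence score threshold; defaults to the detector
#'   config's value.
#' @return data.frame of core diagnoses, invisibly.
#' @export
cmd_infer <- function(config, run_dir = config$out_dir,
                      detector = c("classical", "cnn", "oracle"),
                      split = "test", model = NULL,
                      detection_confidence = NULL) {
  detector <- match.arg(detector)
  conf <- detection_confidence %||% config$detector$detection_confidence
  ds <- load_run_dataset(run_dir)
  ids <- ds$manifest$core_id[ds$manifest$split == split]
  dir.create(file.path(run_dir, "detections"), recursive = TRUE,
             showWarnings = FALSE)
  if (detector == "cnn" && is.null(model)) {
    path <- file.path(run_dir, "model", "model.rds")
    assert_that(file.exists(path), "no trained model state in the run directory")
    model <- readRDS(path)
  }
  per_core <- list()
  for (id in ids) {
    core <- ds$cores[[id]]
    mdl <- switch(detector,
                  classical = classical_params(),
                  cnn = model,
                  oracle = oracle_detector(core$truth))
    insts <- detect(core$phase, mdl, detection_confidence = conf)
    labs <- matrix(0L, ds$shape[1L], ds$shape[2L])
    for (k in seq_along(insts)) labs[insts[[k]]$mask] <- k
    write_label_tiff(labs, file.path(run_dir, "detections",
                                     paste0(id, "_labels.tif")))
    jsonlite::write_json(list(
      core_id = id, detector = detector, detection_confidence = conf,
      instances = lapply(insts, function(x) {
        poly <- x$polygon %||% mask_polygon(x$mask)
        list(class = x$class_label, score = x$score, bbox = x$bbox,
             polygon_rows = poly[, 1L], polygon_cols = poly[, 2L])
      })),
      detections_json_path(run_dir, id), auto_unbox = TRUE, digits = NA)
    per_core[[id]] <- insts
  }
  diagnoses <- diagnose_dataset(per_core, threshold = config$diagnosis_threshold)
  utils::write.csv(diagnoses, file.path(run_dir, "diagnoses.csv"),
                   row.names = FALSE)
  jsonlite::write_json(diagnoses, file.path(run_dir, "diagnoses.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_line(run_dir, "infer(%s, conf %.2f): %d cores, %d indeterminate",
           detector, conf, nrow(diagnoses),
           sum(diagnoses$diagnosis == "indeterminate"))
  invisible(diagnoses)
}

#' Evaluate detections against ground truth
#'
#' Matches the stored detections of the test split to ground truth, and
#' writes the three-level outputs: detection, classification and core
#' confusion matrices (CSV) and the corresponding per-class report tables
#' (CSV + JSON). Cores flagged train or validation are quarantined:
#' requesting them is an error.
#'
#' @param config a [run_config()].
#' @param run_dir run directory holding detections.
#' @param split evaluated split; must be `"test"` unless
#'   `allow_quarantined = TRUE`.
#' @param allow_quarantined override for diagnostic use.
#' @return list with the three confusion matrices and `screening_report`
#'   objects, invisibly.
#' @export
cmd_evaluate <- function(config, run_dir = config$out_dir, split = "test",
                         allow_quarantined = FALSE) {
  if (split != "test" && !allow_quarantined) {
    parameter_error(sprintf(
      "split '%s' is quarantined: evaluation runs on the test split only", split))
  }
  ds <- load_run_dataset(run_dir)
  ids <- ds$manifest$core_id[ds$manifest$split == split]
  eval_dir <- file.path(run_dir, "evaluation")
  dir.create(eval_dir, recursive = TRUE, showWarnings = FALSE)
  matchings <- list(); preds <- list(); truths <- list()
  per_core_pred_labels <- list()
  n_dets <- 0L
  for (id in ids) {
    core <- ds$cores[[id]]
    dj <- detections_json_path(run_dir, id)
    assert_that(file.exists(dj), sprintf("no detections for core '%s'", id),
                format_error)
    det <- jsonlite::read_json(dj)
    labs <- read_label_tiff(file.path(run_dir, "detections",
                                      paste0(id, "_labels.tif")))
    insts <- lapply(seq_along(det$instances), function(k) {
      inst <- det$instances[[k]]
      gland_instance(labs == k, inst$class, score = as.numeric(inst$score))
    })
    n_dets <- n_dets + length(insts)
    m <- match_instances(insts, core$truth$instances, iou_min = config$iou_min)
    matchings[[id]] <- m
    preds[[id]] <- insts
    truths[[id]] <- core$truth$instances
    per_core_pred_labels[[id]] <-
      vapply(insts, `[[`, character(1L), "class_label")
  }
  if (n_dets == 0L) warning("no detections in the evaluated split")
  det_cm <- detection_confusion(unname(matchings), unname(preds), unname(truths))
  cls_cm <- classification_from_detection(det_cm)
  diagnoses <- diagnose_dataset(per_core_pred_labels,
                                threshold = config$diagnosis_threshold)
  truth_lab <- ds$manifest$class_label[match(diagnoses$core_id,
                                             ds$manifest$core_id)]
  core_cm <- confusion_matrix(truth_lab, diagnoses$diagnosis,
                              labels = c("cancer", "normal", "indeterminate"))
  # drop an all-zero indeterminate band so the core table mirrors the
  # two-class layout when the rule is decisive
  if (all(core_cm["indeterminate", ] == 0L) && all(core_cm[, "indeterminate"] == 0L)) {
    core_cm <- core_cm[c("cancer", "normal"), c("cancer", "normal")]
  }
  reports <- list(detection = report(det_cm),
                  classification = report(cls_cm),
                  cores = report(core_cm))
  for (nm in names(reports)) {
    utils::write.csv(as.data.frame(reports[[nm]]),
                     file.path(eval_dir, paste0("report_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(lapply(reports, as.data.frame),
                       file.path(eval_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_cm <- function(cm, name) {
    utils::write.csv(as.data.frame.matrix(cm),
                     file.path(eval_dir, paste0("confusion_", name, ".csv")))
  }
  write_cm(det_cm, "detection"); write_cm(cls_cm, "classification")
  write_cm(core_cm, "cores")
  log_line(run_dir, "evaluate: detection acc %.3f, core acc %.3f",
           reports$detection$accuracy, reports$cores$accuracy)
  invisible(list(detection = det_cm, classification = cls_cm, cores = core_cm,
                 reports = reports))
}
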