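# Dataset assembly: per-class split allocation and core materialization.

#' Allocate cores of one class across train/validation/test
#'
#' Two rules are available. `"balanced"` (default) gives train and
#' validation the same number of cores from every class —
#' `round(total * fraction / n_classes)` each — and assigns each class's
#' remainder to test; with two classes and fractions (0.76, 0.12, 0.12) on
#' 127 cancer + 131 normal cores this yields the canonical 98/98, 15/15,
#' 14/18 composition (totals 196/30/32). `"proportional"` splits each class
#' by largest-remainder rounding of its own size.
#'
#' @keywords internal
allocate_splits <- function(n_class, n_total, fractions, allocation, n_classes = 2L) {
  if (n_class == 0L) return(c(train = 0L, validation = 0L, test = 0L))
  if (allocation == "balanced") {
    tr <- min(round(n_total * fractions[1L] / n_classes), n_class)
    va <- min(round(n_total * fractions[2L] / n_classes), n_class - tr)
    c(train = as.integer(tr), validation = as.integer(va),
      test = as.integer(n_class - tr - va))
  } else {
    raw <- n_class * fractions
    base <- floor(raw)
    rem <- raw - base
    left <- n_class - sum(base)
    if (left > 0L) {
      give <- order(rem, decreasing = TRUE)[seq_len(left)]
      base[give] <- base[give] + 1L
    }
    stats::setNames(as.integer(base), c("train", "validation", "test"))
  }
}

#' Generate a synthetic TMA dataset with splits
#'
#' Creates `n_cancer + n_normal` synthetic core descriptors, assigns each a
#' reproducible child seed, and partitions them into train/validation/test.
#' With the default `"balanced"` allocation, train and validation are
#' class-balanced and test absorbs each class's remainder. Cores are
#' rendered lazily via [materialize_core()] (or eagerly with
#' `materialize = TRUE`), so large datasets can be split without rendering.
#'
#' @param n_cancer number of cancer cores.
#' @param n_normal number of normal cores.
#' @param fractions numeric `(train, validation, test)` fractions summing
#'   to 1 (within 1e-9).
#' @param seed integer seed governing split shuffling and every core's
#'   content.
#' @param allocation `"balanced"` or `"proportional"`; see
#'   [allocate_splits()].
#' @param composition optional explicit per-class split counts overriding
#'   the allocation rule: a list like
#'   `list(cancer = c(train=98, validation=15, test=14), normal = ...)`.
#' @param shape image shape for rendered cores.
#' @param materialize if `TRUE`, render every core now (`$cores`).
#' @return an object of class `tma_dataset`: `manifest` (data.frame with
#'   `core_id`, `class_label`, `split`, `seed`), `splits` (list of id
#'   vectors), `fractions`, `shape`, and optionally `cores`.
#' @export
generate_dataset <- function(n_cancer, n_normal,
                             fractions = c(0.76, 0.12, 0.12), seed = NULL,
                             allocation = c("balanced", "proportional"),
                             composition = NULL, shape = c(256L, 256L),
                             materialize = FALSE) {
  allocation <- match.arg(allocation)
  assert_that(is_scalar_number(n_cancer) && n_cancer >= 0 &&
                is_scalar_number(n_normal) && n_normal >= 0,
              "core counts must be non-negative")
  assert_that(length(fractions) == 3L && all(fractions >= 0) &&
                abs(sum(fractions) - 1) < 1e-9,
              "fractions must be (train, validation, test) summing to 1")
  n_cancer <- as.integer(n_cancer); n_normal <- as.integer(n_normal)
  total <- n_cancer + n_normal
  counts <- c(cancer = n_cancer, normal = n_normal)
  splits <- c("train", "validation", "test")

  manifest <- data.frame(core_id = character(0), class_label = character(0),
                         split = character(0), seed = integer(0),
                         stringsAsFactors = FALSE)
  if (total > 0L) {
    ids <- sprintf("core_%04d", seq_len(total))
    class_label <- rep(c("cancer", "normal"), times = counts)
    assign <- with_local_seed(seed, {
      out <- character(total)
      for (cl in names(counts)) {
        n_cl <- counts[[cl]]
        if (n_cl == 0L) next
        alloc <- if (!is.null(composition)) {
          cmp <- composition[[cl]]
          assert_that(!is.null(cmp) && sum(cmp) == n_cl,
                      sprintf("composition for class '%s' must sum to %d", cl, n_cl))
          stats::setNames(as.integer(cmp[splits]), splits)
        } else {
          allocate_splits(n_cl, total, fractions, allocation)
        }
        lab <- rep(splits, times = alloc)
        out[class_label == cl] <- sample(lab)
      }
      out
    })
    manifest <- data.frame(core_id = ids, class_label = class_label,
                           split = assign,
                           seed = vapply(seq_len(total), function(i)
                             derive_seed(if (is.null(seed)) 0L else seed, i),
                             integer(1L)),
                           stringsAsFactors = FALSE)
  }
  ds <- structure(list(
    manifest = manifest,
    splits = lapply(stats::setNames(splits, splits), function(s)
      manifest$core_id[manifest$split == s]),
    fractions = fractions, shape = as.integer(shape), allocation = allocation
  ), class = "tma_dataset")
  if (materialize && total > 0L) {
    ds$cores <- lapply(manifest$core_id, function(id) materialize_core(ds, id))
    names(ds$cores) <- manifest$core_id
  }
  ds
}

#' Render one core of a dataset
#'
#' Reproducibly renders the phase map and ground truth of a dataset core
#' from its manifest row (class preset + per-core seed). The rare preset
#' draw whose boundaries overlap beyond the tolerated fusion fraction is
#' re-drawn deterministically from the next derived seed, so dataset
#' materialization always succeeds and stays reproducible.
#'
#' @param dataset a `tma_dataset` from [generate_dataset()].
#' @param core_id core identifier from the manifest.
#' @return list with `phase` and `truth` as in [render_core()].
#' @export
materialize_core <- function(dataset, core_id) {
  row <- dataset$manifest[dataset$manifest$core_id == core_id, , drop = FALSE]
  assert_that(nrow(row) == 1L, sprintf("unknown core id '%s'", core_id))
  for (attempt in 0:19) {
    seed <- derive_seed(row$seed, attempt * 613L)
    specs <- core_preset(row$class_label, shape = dataset$shape, seed = seed)
    core <- tryCatch(
      render_core(specs, shape = dataset$shape, seed = derive_seed(seed, 1L),
                  core_id = core_id, core_label = row$class_label),
      slimscreen_generation_error = function(e) NULL)
    if (!is.null(core)) return(core)
  }
  generation_error(sprintf("core '%s': no acceptable gland layout in 20 draws",
                           core_id))
}

#' @export
print.tma_dataset <- function(x, ...) {
  tab <- table(x$manifest$split, x$manifest$class_label)
  cat(sprintf("<tma_dataset> %d cores (%s allocation)\n",
              nrow(x$manifest), x$allocation))
  if (nrow(x$manifest)) print(tab)
  invisible(x)
}
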