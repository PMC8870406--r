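# Core-level diagnosis: aggregate per-gland classifications by the 90% rule.

#' Classify a core from its gland labels
#'
#' A core is diagnosed cancer when at least `threshold` of its glands are
#' cancer, normal when at least `threshold` are normal, and indeterminate
#' otherwise (including the zero-gland case). With the default inclusive
#' convention, "90%+" means a fraction of exactly 0.90 qualifies.
#'
#' @param labels character vector of gland labels, each `"cancer"` or
#'   `"normal"`.
#' @param threshold diagnosis threshold in (0.5, 1]; default 0.90.
#' @param inclusive if `TRUE` (default) the comparison is `>=`; strict `>`
#'   otherwise.
#' @return an object of class `core_diagnosis`: `label` (`"cancer"`,
#'   `"normal"` or `"indeterminate"`), `n_glands`, `cancer_fraction`,
#'   `threshold`.
#' @export
classify_core <- function(labels, threshold = 0.90, inclusive = TRUE) {
  assert_that(is_scalar_number(threshold) && threshold > 0.5 && threshold <= 1,
              "threshold must be in (0.5, 1]")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("cancer", "normal"))
  if (length(bad)) {
    format_error(sprintf("unknown gland label(s): %s", paste(bad, collapse = ", ")))
  }
  n <- length(labels)
  frac <- if (n > 0L) mean(labels == "cancer") else NA_real_
  cmp <- if (inclusive) `>=` else `>`
  label <- if (n == 0L) "indeterminate"
  else if (cmp(frac, threshold)) "cancer"
  else if (cmp(1 - frac, threshold)) "normal"
  else "indeterminate"
  structure(list(label = label, n_glands = n,
                 cancer_fraction = if (n > 0L) frac else 0,
                 threshold = threshold),
            class = "core_diagnosis")
}

#' @export
print.core_diagnosis <- function(x, ...) {
  cat(sprintf("<core_diagnosis> %s (%d glands, cancer fraction %.2f, threshold %.2f)\n",
              x$label, x$n_glands, x$cancer_fraction, x$threshold))
  invisible(x)
}

#' Diagnose every core of a dataset
#'
#' @param per_core_labels named list: for each core id, either a character
#'   vector of gland labels or a list of [gland_instance()] objects.
#' @param threshold diagnosis threshold, passed to [classify_core()].
#' @param inclusive comparison convention, passed to [classify_core()].
#' @return data.frame ordered by core id with columns `core_id`, `n_glands`,
#'   `cancer_fraction`, `diagnosis`.
#' @export
diagnose_dataset <- function(per_core_labels, threshold = 0.90, inclusive = TRUE) {
  if (length(per_core_labels) == 0L) {
    return(data.frame(core_id = character(0), n_glands = integer(0),
                      cancer_fraction = numeric(0), diagnosis = character(0),
                      stringsAsFactors = FALSE))
  }
  ids <- names(per_core_labels)
  assert_that(!is.null(ids) && all(nzchar(ids)),
              "per-core detections must be named by core id", format_error)
  if (anyDuplicated(ids)) {
    format_error(sprintf("duplicate core id(s): %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  ord <- order(ids)
  rows <- lapply(ord, function(i) {
    x <- per_core_labels[[i]]
    labels <- if (is.character(x)) x
    else vapply(x, function(inst) inst$class_label, character(1L))
    d <- classify_core(labels, threshold = threshold, inclusive = inclusive)
    data.frame(core_id = ids[i], n_glands = d$n_glands,
               cancer_fraction = d$cancer_fraction, diagnosis = d$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
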