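# Reference confusion counts shipped with the package.

#' Load the reference confusion counts
#'
#' Confusion counts from a label-free colorectal screening experiment
#' (132-patient tissue microarray, 32 held-out test cores), shipped as
#' plain-CSV fixtures. `"detection"` is the gland-detection matrix with the
#' stroma/background pseudo-class; `"classification"` is the same matrix
#' restricted to detected glands; `"cores"` is the core-diagnosis matrix.
#'
#' @param which one of `"detection"`, `"classification"`, `"cores"`.
#' @return integer confusion matrix (rows = actual, columns = predicted).
#' @export
reference_counts <- function(which = c("detection", "classification", "cores")) {
  which <- match.arg(which)
  file <- if (which == "cores") "core_confusion.csv" else "detection_confusion.csv"
  path <- system.file("extdata", "reference_counts", file, package = "slimscreen",
                      mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(actual = df[[1L]], predicted = colnames(df)[-1L])
  if (which == "classification") m <- classification_from_detection(m)
  m
}
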