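# Scanline polygon rasterization.
#
# Pixel convention: 0-based, row-major; pixel (i, j) is the unit cell whose
# center sits at coordinates (i, j). A pixel belongs to the polygon when its
# center is inside under the even-odd rule, with half-open handling of exact
# crossings (a center lying exactly on a right/bottom crossing is excluded),
# matching the half-open [r0, r1) x [c0, c1) box convention used throughout.

#' Rasterize a closed polygon into a logical mask
#'
#' @param vertices numeric matrix with columns (row, col): polygon vertices in
#'   0-based pixel coordinates. The polygon is closed implicitly (last vertex
#'   connects back to the first) and must be simple.
#' @param shape integer vector `(rows, cols)` of the output mask.
#' @return logical matrix of dimension `shape`; `TRUE` inside the polygon.
#' @export
rasterize_polygon <- function(vertices, shape) {
  assert_that(is.matrix(vertices) && ncol(vertices) == 2L && nrow(vertices) >= 3L,
              "vertices must be an n x 2 matrix with n >= 3")
  assert_that(length(shape) == 2L && all(shape >= 1L), "shape must be (rows, cols)")
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  out <- matrix(FALSE, nr, nc)
  vr <- vertices[, 1L]; vc <- vertices[, 2L]
  nxt <- c(seq_len(nrow(vertices))[-1L], 1L)
  wr <- vr[nxt]; wc <- vc[nxt]
  lo <- max(0L, floor(min(vr)))
  hi <- min(nr - 1L, ceiling(max(vr)))
  if (lo > hi) return(out)
  for (y in lo:hi) {
    # edges crossing the horizontal line through row-centers y (half-open in y)
    cross <- (vr <= y & wr > y) | (wr <= y & vr > y)
    if (!any(cross)) next
    t <- (y - vr[cross]) / (wr[cross] - vr[cross])
    xs <- sort(vc[cross] + t * (wc[cross] - vc[cross]))
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      a <- max(ceiling(xs[k]), 0)
      b <- min(ceiling(xs[k + 1L]) - 1, nc - 1)
      if (a <= b) out[y + 1L, (a:b) + 1L] <- TRUE
    }
  }
  out
}
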