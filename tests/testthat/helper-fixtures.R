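# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

# Render (and cache) a preset core at a given scale.
fixture_core <- function(class_label, seed, shape = c(512L, 512L)) {
  key <- paste(class_label, seed, paste(shape, collapse = "x"), sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  specs <- core_preset(class_label, shape = shape, seed = seed)
  core <- render_core(specs, shape = shape, seed = seed + 5000L,
                      core_id = key, core_label = class_label)
  .fixture_cache[[key]] <- core
  core
}

# A mixed bag of rendered cores, alternating cancer/normal.
fixture_core_set <- function(n, shape = c(512L, 512L), seed_base = 9100L) {
  lapply(seq_len(n), function(i) {
    fixture_core(if (i %% 2L) "cancer" else "normal", seed_base + i, shape)
  })
}

# Independent point-in-polygon test (ray crossing, per pixel center),
# structurally different from the scanline implementation.
point_in_polygon <- function(py, px, vr, vc) {
  n <- length(vr)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vr[i] <= py) != (vr[j] <= py)) {
      xint <- vc[i] + (py - vr[i]) / (vr[j] - vr[i]) * (vc[j] - vc[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(vertices, shape) {
  out <- matrix(FALSE, shape[1L], shape[2L])
  for (i in seq_len(shape[1L])) {
    for (j in seq_len(shape[2L])) {
      out[i, j] <- point_in_polygon(i - 1L, j - 1L, vertices[, 1L], vertices[, 2L])
    }
  }
  out
}

# Random blob masks for matching tests: filled circles with random centers.
random_masks <- function(n, shape, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cy <- runif(1, 10, shape[1L] - 10); cx <- runif(1, 10, shape[2L] - 10)
      r <- runif(1, 4, 12)
      rows <- matrix(seq_len(shape[1L]) - 1, shape[1L], shape[2L])
      cols <- matrix(rep(seq_len(shape[2L]) - 1, each = shape[1L]),
                     shape[1L], shape[2L])
      (rows - cy)^2 + (cols - cx)^2 <= r^2
    })
  })
}
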