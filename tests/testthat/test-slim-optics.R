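# Four-frame simulation, phase retrieval, mosaic stitching.

random_model <- function(seed, shape = c(16, 16), beta_range = c(0.2, 0.9)) {
  withr::with_seed(seed, {
    field_model(
      u0_intensity = matrix(runif(prod(shape), 0.5, 2), shape[1]),
      beta = matrix(runif(prod(shape), beta_range[1], beta_range[2]), shape[1]),
      delta_phi = matrix(runif(prod(shape), -pi, pi), shape[1]))
  })
}

test_that("frames follow the interferometric forward model", {
  # beta = 0: no scattered field, all frames equal |U0|^2
  m0 <- field_model(matrix(1.5, 4, 4), matrix(0, 4, 4), matrix(0.7, 4, 4))
  fs <- simulate_frames(m0)
  for (f in fs$frames) expect_equal(f, matrix(1.5, 4, 4))

  # dphi = 0, beta = 1, |U0|^2 = 1: frames are (4, 2, 0, 2)
  m1 <- field_model(matrix(1, 2, 2), matrix(1, 2, 2), matrix(0, 2, 2))
  fs1 <- simulate_frames(m1)
  expect_equal(vapply(fs1$frames, function(f) f[1, 1], numeric(1)),
               c(4, 2, 0, 2))

  # quadrature identities at every pixel
  m <- random_model(31)
  fs2 <- simulate_frames(m)
  expect_equal(fs2$frames[[1]] - fs2$frames[[3]],
               4 * m$u0_intensity * m$beta * cos(m$delta_phi))
  expect_equal(fs2$frames[[4]] - fs2$frames[[2]],
               4 * m$u0_intensity * m$beta * sin(m$delta_phi))
})

test_that("noiseless retrieval inverts the forward model to machine precision", {
  worst_phi <- 0; worst_beta <- 0
  for (s in 1:50) {
    m <- random_model(s)
    ret <- retrieve_phase(simulate_frames(m))
    worst_phi <- max(worst_phi, max(abs(ret$phase$phase - model_phase(m))))
    worst_beta <- max(worst_beta, max(abs(ret$beta - m$beta) / m$beta))
  }
  expect_lt(worst_phi, 1e-9)
  expect_lt(worst_beta, 1e-6)
})

test_that("degenerate frames are flagged instead of dividing by zero", {
  fs <- frame_stack(lapply(c(4, 2, 0, 2), function(v) matrix(v, 3, 3)))
  ret <- retrieve_phase(fs)
  expect_equal(ret$phase$phase, matrix(0, 3, 3))

  uni <- frame_stack(replicate(4, matrix(2, 3, 3), simplify = FALSE))
  ret2 <- retrieve_phase(uni)
  expect_true(all(ret2$low_modulation))
  expect_equal(ret2$phase$phase, matrix(0, 3, 3))
})

test_that("retrieval error grows with detector noise", {
  m <- random_model(77, shape = c(32, 32))
  truth <- model_phase(m)
  sds <- seq(0.01, 0.5, length.out = 10)
  errs <- vapply(seq_along(sds), function(i) {
    ret <- retrieve_phase(simulate_frames(m, noise_sd = sds[i], seed = 100 + i))
    mean(abs(ret$phase$phase - truth))
  }, numeric(1))
  expect_gt(cor(sds, errs, method = "spearman"), 0.9)
})

test_that("frame-stack validation rejects malformed input", {
  expect_error(frame_stack(list(matrix(1, 2, 2), matrix(1, 2, 2))),
               class = "slimscreen_format_error")
  expect_error(frame_stack(list(matrix(1, 2, 2), matrix(1, 2, 2),
                                matrix(1, 2, 2), matrix(1, 3, 3))),
               class = "slimscreen_format_error")
  expect_error(simulate_frames(random_model(1), noise_sd = -1),
               class = "slimscreen_parameter_error")
})

test_that("stitching identities: 1x1, zero-overlap grid arithmetic, cut-then-stitch", {
  pm <- phase_map(matrix(runif(128 * 128, -1, 1), 128))
  expect_equal(stitch_tiles(list(pm), c(1, 1), 0)$phase, pm$phase)

  tiles16 <- replicate(16, phase_map(matrix(0.3, 128, 128)), simplify = FALSE)
  expect_identical(dim(stitch_tiles(tiles16, c(4, 4), 0)$phase), c(512L, 512L))

  big <- phase_map(matrix(rnorm(120 * 120), 120), unwrapped = TRUE)
  for (o in c(0L, 8L)) {
    layout <- c(2L, 2L)
    tile <- (120L - o) / 2L + o
    tiles <- list()
    step <- tile - o
    for (i in 1:2) for (j in 1:2) {
      tiles[[length(tiles) + 1]] <- phase_map(
        big$phase[(i - 1) * step + seq_len(tile), (j - 1) * step + seq_len(tile)],
        unwrapped = TRUE)
    }
    st <- stitch_tiles(tiles, layout, o)
    expect_equal(st$phase, big$phase, tolerance = 1e-12)
  }
})

test_that("ragged tile grids are rejected", {
  tiles <- replicate(3, phase_map(matrix(0, 16, 16)), simplify = FALSE)
  expect_error(stitch_tiles(tiles, c(2, 2), 0), class = "slimscreen_format_error")
  bad <- c(replicate(3, phase_map(matrix(0, 16, 16)), simplify = FALSE),
           list(phase_map(matrix(0, 8, 8))))
  expect_error(stitch_tiles(bad, c(2, 2), 0), class = "slimscreen_format_error")
})
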