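# Anchor generation, augmentation, the classical segmenter, detection
# thresholds.

test_that("anchor grid emits 15 boxes per point with the right geometry", {
  cfg <- detector_config()
  a1 <- generate_anchors(cfg, feature_stride = 64, image_shape = c(64, 64))
  expect_identical(nrow(a1), 15L)

  sq <- a1[a1$scale == 8 & a1$ratio == 1, ]
  expect_equal(sq$r1 - sq$r0, 8)
  expect_equal(sq$c1 - sq$c0, 8)
  expect_equal((sq$r0 + sq$r1) / 2, 32)

  # area s^2 for every (scale, ratio) pair
  expect_equal((a1$r1 - a1$r0) * (a1$c1 - a1$c0), a1$scale^2, tolerance = 1e-9)

  a2 <- generate_anchors(cfg, feature_stride = 32, image_shape = c(128, 256))
  expect_identical(nrow(a2), as.integer(4 * 8 * 15))
  expect_error(generate_anchors(cfg, feature_stride = 48, image_shape = c(128, 128)),
               class = "slimscreen_parameter_error")
})

test_that("identity policy and flip involution behave as transforms should", {
  img <- matrix(rnorm(32 * 32), 32)
  msk <- list(matrix(rep(c(TRUE, FALSE), each = 512), 32))
  idp <- augmentation_policy(hflip_prob = 0, vflip_prob = 0, rotations = 90,
                            blur_sigma_range = c(0, 0))
  idp$rotations <- numeric(0)  # no rotation choices at all
  out <- augment(img, msk, idp, seed = 1)
  expect_identical(out$image, img)
  expect_identical(out$masks, msk)

  flip <- augmentation_policy(hflip_prob = 1, vflip_prob = 0, rotations = 90,
                              blur_sigma_range = c(0, 0))
  flip$rotations <- numeric(0)
  once <- augment(img, msk, flip, seed = 2)
  twice <- augment(once$image, once$masks, flip, seed = 3)
  expect_identical(twice$image, img)
  expect_identical(twice$masks, msk)
})

test_that("geometric augmentation preserves instance count and mask areas", {
  core <- fixture_core("normal", 21, shape = c(128L, 128L))
  masks <- lapply(core$truth$instances, `[[`, "mask")
  pol <- augmentation_policy()
  for (s in 1:100) {
    out <- augment(core$phase, masks, pol, seed = s)
    expect_identical(length(out$masks), length(masks))
    expect_identical(vapply(out$masks, sum, integer(1)),
                     vapply(masks, sum, integer(1)))
  }
  # determinism under a fixed seed
  o1 <- augment(core$phase, masks, pol, seed = 12)
  o2 <- augment(core$phase, masks, pol, seed = 12)
  expect_identical(o1$image$phase, o2$image$phase)
})

test_that("classical segmenter: stroma-only empty, single circle is one normal", {
  stroma <- render_core(list(), shape = c(128, 128), seed = 3)
  expect_length(classical_segment(stroma$phase), 0L)

  spec <- gland_spec(c(64, 64), 30, "normal", irregularity = 0,
                     lumen_fraction = 0.5, phase_amplitude = 1.8)
  core <- render_core(list(spec), shape = c(128, 128), seed = 4)
  insts <- classical_segment(core$phase)
  expect_length(insts, 1L)
  expect_identical(insts[[1]]$class_label, "normal")
  expect_gt(mask_iou(insts[[1]]$mask, core$truth$instances[[1]]$mask), 0.5)

  expect_error(classical_segment(matrix(c(1, NA, 1, 1), 2)),
               class = "slimscreen_format_error")
})

test_that("classical segmenter is byte-identical across runs", {
  core <- fixture_core("cancer", 31, shape = c(256L, 256L))
  a <- classical_segment(core$phase)
  b <- classical_segment(core$phase)
  expect_identical(a, b)
})

test_that("detections at higher confidence nest inside lower-confidence ones", {
  cores <- fixture_core_set(6, shape = c(256L, 256L), seed_base = 9300L)
  key <- function(x) paste(x$bbox, collapse = ",")
  for (core in cores) {
    d7 <- detect(core$phase, classical_params(), 0.7)
    d9 <- detect(core$phase, classical_params(), 0.9)
    expect_true(all(vapply(d9, key, character(1)) %in%
                      vapply(d7, key, character(1))))
    expect_lte(length(d9), length(d7))
    scores <- vapply(d7, `[[`, numeric(1), "score")
    expect_true(all(diff(scores) <= 0))
  }
})

test_that("detect handles limits: oracle echo, threshold 1, empty core", {
  core <- fixture_core("normal", 41, shape = c(128L, 128L))
  od <- oracle_detector(core$truth)
  got <- detect(core$phase, od, 0.9)
  expect_length(got, length(core$truth$instances))
  expect_length(detect(core$phase, od, 1.0), length(core$truth$instances))

  cl <- detect(core$phase, classical_params(), 1.0)
  expect_true(all(vapply(cl, `[[`, numeric(1), "score") == 1))

  stroma <- render_core(list(), shape = c(128, 128), seed = 6)
  expect_length(detect(stroma$phase, classical_params(), 0.7), 0L)
})

test_that("non-maximum suppression keeps the highest-scoring of overlapping boxes", {
  m1 <- matrix(FALSE, 32, 32); m1[5:20, 5:20] <- TRUE
  m2 <- matrix(FALSE, 32, 32); m2[6:21, 6:21] <- TRUE
  m3 <- matrix(FALSE, 32, 32); m3[25:30, 25:30] <- TRUE
  insts <- list(gland_instance(m1, "normal", 0.8),
                gland_instance(m2, "cancer", 0.9),
                gland_instance(m3, "normal", 0.5))
  kept <- nms_instances(insts, iou = 0.3)
  expect_length(kept, 2L)
  expect_identical(kept[[1]]$score, 0.9)
})
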