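# Synthetic core generation: boundary sampling, rasterization, rendering,
# dataset splits.

test_that("zero-irregularity boundary is an exact circle, seeded draws repeat", {
  spec <- gland_spec(c(100, 100), 40, "normal", irregularity = 0)
  poly <- sample_gland_shape(spec, seed = 1)
  radii <- sqrt(rowSums(sweep(poly, 2, c(100, 100))^2))
  expect_lt(max(abs(radii - 40)), 0.01 * 40)

  spec2 <- gland_spec(c(100, 100), 40, "cancer", irregularity = 0.8)
  p1 <- sample_gland_shape(spec2, seed = 42)
  p2 <- sample_gland_shape(spec2, seed = 42)
  expect_identical(p1, p2)
  expect_false(identical(p1, sample_gland_shape(spec2, seed = 43)))
})

test_that("boundary roughness increases with the irregularity knob", {
  roughness <- function(irr, seed) {
    spec <- gland_spec(c(0, 0), 40, "cancer", irregularity = irr)
    poly <- sample_gland_shape(spec, seed = seed)
    r <- sqrt(rowSums(poly^2))
    sd(r) / mean(r)
  }
  r_low <- vapply(1:200, function(s) roughness(0.1, s), numeric(1))
  r_high <- vapply(1:200, function(s) roughness(0.8, s), numeric(1))
  expect_gt(mean(r_high), mean(r_low))
  # mean radial distance stays pinned to base_radius
  spec <- gland_spec(c(0, 0), 40, "cancer", irregularity = 0.8)
  poly <- sample_gland_shape(spec, seed = 3)
  expect_lt(abs(mean(sqrt(rowSums(poly^2))) - 40) / 40, 0.2)
})

test_that("scanline rasterization agrees with a point-in-polygon oracle", {
  for (s in 1:5) {
    spec <- gland_spec(c(30, 32), 18, "cancer", irregularity = 0.6)
    poly <- sample_gland_shape(spec, seed = s)
    got <- rasterize_polygon(poly, c(64, 64))
    want <- oracle_rasterize(poly, c(64, 64))
    expect_identical(got, want)
  }
})

test_that("rendered instance mask equals ring polygon minus lumen (oracle count)", {
  spec <- gland_spec(c(48, 48), 22, "normal", irregularity = 0,
                     lumen_fraction = 0.5)
  core <- render_core(list(spec), shape = c(96, 96), seed = 7)
  expect_length(core$truth$instances, 1L)
  outer_poly <- sample_gland_shape(spec)
  lumen_poly <- slimscreen:::scale_polygon(outer_poly, spec$center, 0.5)
  want <- oracle_rasterize(outer_poly, c(96, 96)) &
    !oracle_rasterize(lumen_poly, c(96, 96))
  expect_identical(sum(core$truth$instances[[1]]$mask), sum(want))
})

test_that("rendering is deterministic and respects phase/mask invariants", {
  specs <- core_preset("cancer", shape = c(128, 128), seed = 11)
  a <- render_core(specs, shape = c(128, 128), seed = 12)
  b <- render_core(specs, shape = c(128, 128), seed = 12)
  expect_identical(a$phase$phase, b$phase$phase)
  expect_identical(label_image(a$truth), label_image(b$truth))

  expect_true(all(is.finite(a$phase$phase)))
  expect_true(all(a$phase$phase > -pi & a$phase$phase <= pi))
  # per-pixel instance multiplicity never exceeds 1
  acc <- Reduce(`+`, lapply(a$truth$instances, function(i) i$mask + 0L))
  expect_lte(max(acc), 1L)
  # stroma has lower mean phase than epithelial rings
  rings <- acc > 0
  expect_gt(mean(a$phase$phase[rings]), mean(a$phase$phase[!rings]))
  # preset consistency
  expect_true(all(vapply(a$truth$instances, `[[`, character(1), "class_label") ==
                    "cancer"))
  expect_identical(a$truth$core_label, "cancer")
})

test_that("empty spec list renders pure stroma", {
  core <- render_core(list(), shape = c(64, 64), seed = 1)
  expect_length(core$truth$instances, 0L)
  expect_true(all(is.finite(core$phase$phase)))
})

test_that("grossly overlapping glands raise a generation error", {
  s1 <- gland_spec(c(60, 60), 25, "normal", irregularity = 0)
  s2 <- gland_spec(c(62, 60), 25, "normal", irregularity = 0)
  expect_error(render_core(list(s1, s2), shape = c(128, 128), seed = 1),
               class = "slimscreen_generation_error")
})

test_that("roughness statistic separates the two gland classes (AUC > 0.8)", {
  cores <- fixture_core_set(12)
  roughs <- c(); labs <- c()
  for (core in cores) {
    r <- vapply(core$truth$instances, function(i) roughness_statistic(i$mask),
                numeric(1))
    roughs <- c(roughs, r)
    labs <- c(labs, vapply(core$truth$instances, `[[`, character(1),
                           "class_label") == "cancer")
  }
  expect_gte(length(roughs), 60L)
  expect_gt(roc_auc(roughs, labs), 0.8)
})

test_that("balanced allocation reproduces the canonical 258-core composition", {
  ds <- generate_dataset(127, 131, c(0.76, 0.12, 0.12), seed = 5)
  sizes <- vapply(ds$splits, length, integer(1))
  expect_identical(sizes, c(train = 196L, validation = 30L, test = 32L))
  tab <- table(ds$manifest$split, ds$manifest$class_label)
  expect_identical(as.integer(tab["train", ]), c(98L, 98L))
  expect_identical(as.integer(tab["validation", ]), c(15L, 15L))
  expect_identical(as.integer(tab["test", ]), c(14L, 18L))
  expect_equal(sizes[["train"]] / 258, 0.76, tolerance = 0.005)
})

test_that("splits are disjoint and exhaustive across random sizes and seeds", {
  for (s in 1:50) {
    set.seed(s)
    nc <- sample(0:40, 1); nn <- sample(0:40, 1)
    ds <- generate_dataset(nc, nn, seed = s,
                           allocation = sample(c("balanced", "proportional"), 1))
    ids <- unlist(ds$splits)
    expect_identical(anyDuplicated(ids), 0L)
    expect_identical(length(ids), nc + nn)
    expect_setequal(ids, ds$manifest$core_id)
  }
})

test_that("per-split class counts stay within 2 of the requested allocation", {
  ds <- generate_dataset(50, 50, c(0.6, 0.2, 0.2), seed = 9)
  tab <- table(ds$manifest$split, ds$manifest$class_label)
  want <- c(train = 30, validation = 10, test = 10)
  for (s in rownames(tab)) {
    expect_lte(max(abs(tab[s, ] - want[[s]])), 2)
  }
})

test_that("empty dataset yields empty splits without error", {
  ds <- generate_dataset(0, 0, seed = 1)
  expect_true(all(vapply(ds$splits, length, integer(1)) == 0L))
})

test_that("explicit composition override is honored", {
  ds <- generate_dataset(10, 8, seed = 2, composition = list(
    cancer = c(train = 6, validation = 2, test = 2),
    normal = c(train = 4, validation = 2, test = 2)))
  tab <- table(ds$manifest$split, ds$manifest$class_label)
  expect_identical(as.integer(tab[c("train", "validation", "test"), "cancer"]),
                   c(6L, 2L, 2L))
})
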