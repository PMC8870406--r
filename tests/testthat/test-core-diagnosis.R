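# Core-level diagnosis by the 90% gland-vote rule.

test_that("the 90% rule assigns cancer, normal and indeterminate correctly", {
  expect_identical(classify_core(rep("cancer", 10))$label, "cancer")
  expect_identical(classify_core(rep("normal", 10))$label, "normal")
  expect_identical(classify_core(character(0))$label, "indeterminate")
  # boundary: 9 of 10 cancer is exactly 0.90 -> cancer under the inclusive rule
  labels <- c(rep("cancer", 9), "normal")
  expect_identical(classify_core(labels)$label, "cancer")
  expect_identical(classify_core(labels, inclusive = FALSE)$label, "indeterminate")
  expect_identical(classify_core(c(rep("cancer", 5), rep("normal", 5)))$label,
                   "indeterminate")
  expect_error(classify_core(c("cancer", "stroma")),
               class = "slimscreen_format_error")
  expect_error(classify_core("cancer", threshold = 0.4),
               class = "slimscreen_parameter_error")
})

test_that("diagnosis is symmetric under label swap and permutation invariant", {
  swap <- function(x) c(cancer = "normal", normal = "cancer")[x]
  for (s in 1:20) {
    set.seed(s)
    labels <- sample(c("cancer", "normal"), sample(1:30, 1), replace = TRUE)
    d <- classify_core(labels)$label
    d_swap <- classify_core(unname(swap(labels)))$label
    expect_identical(d_swap, if (d == "indeterminate") d else unname(swap(d)))
    expect_identical(classify_core(sample(labels))$label, d)
  }
})

test_that("near-majority threshold only leaves exact ties indeterminate", {
  eps_thr <- 0.5 + 1e-9
  expect_identical(classify_core(c("cancer", "cancer", "normal"), eps_thr)$label,
                   "cancer")
  expect_identical(classify_core(c("cancer", "normal"), eps_thr)$label,
                   "indeterminate")
})

test_that("dataset diagnosis is order-stable, rejects duplicates, matches oracle", {
  # canonical test composition with oracle gland labels
  per_core <- c(
    lapply(1:14, function(i) rep("cancer", 5 + i %% 3)),
    lapply(1:18, function(i) rep("normal", 4 + i %% 4)))
  names(per_core) <- c(sprintf("tumor_%02d", 1:14), sprintf("benign_%02d", 1:18))
  d <- diagnose_dataset(per_core)
  expect_identical(nrow(d), 32L)
  expect_identical(sum(d$diagnosis == "cancer"), 14L)
  expect_identical(sum(d$diagnosis == "normal"), 18L)
  expect_identical(d$core_id, sort(names(per_core)))

  per_core$benign_01 <- c(rep("cancer", 3), rep("normal", 3))
  d2 <- diagnose_dataset(per_core)
  expect_identical(d2$diagnosis[d2$core_id == "benign_01"], "indeterminate")

  dup <- per_core[c(1, 1)]
  expect_error(diagnose_dataset(dup), class = "slimscreen_format_error")
})

test_that("indeterminate count is non-decreasing along a threshold sweep", {
  set.seed(14)
  per_core <- lapply(1:32, function(i)
    sample(c("cancer", "normal"), sample(2:25, 1), replace = TRUE,
           prob = c(runif(1), 1)))
  names(per_core) <- sprintf("core_%02d", 1:32)
  counts <- vapply(seq(0.6, 1.0, by = 0.05), function(th)
    sum(diagnose_dataset(per_core, threshold = th)$diagnosis == "indeterminate"),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})
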