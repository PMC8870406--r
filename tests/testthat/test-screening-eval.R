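# Instance matching, confusion matrices, report tables, sweeps, ROC/AUC.

test_that("matching identities: self-match at IoU 1, disjoint masks unmatched", {
  masks <- random_masks(4, c(64, 64), seed = 1)
  insts <- lapply(masks, function(m) gland_instance(m, "normal", 0.9))
  m <- match_instances(insts, insts)
  expect_identical(nrow(m$pairs), 4L)
  expect_true(all(m$pairs$iou == 1))
  expect_length(m$unmatched_preds, 0L)

  a <- matrix(FALSE, 32, 32); a[1:5, 1:5] <- TRUE
  b <- matrix(FALSE, 32, 32); b[20:25, 20:25] <- TRUE
  m2 <- match_instances(list(gland_instance(a, "cancer", 1)),
                        list(gland_instance(b, "cancer", 1)))
  expect_identical(nrow(m2$pairs), 0L)
  expect_identical(m2$unmatched_preds, 1L)
  expect_identical(m2$unmatched_truths, 1L)
})

test_that("greedy matching equals an independent greedy oracle on random masks", {
  greedy_oracle <- function(preds, truths, iou_min) {
    iou_mat <- outer(seq_along(preds), seq_along(truths),
                     Vectorize(function(i, j) {
                       inter <- sum(preds[[i]]$mask & truths[[j]]$mask)
                       uni <- sum(preds[[i]]$mask | truths[[j]]$mask)
                       if (uni == 0) 0 else inter / uni
                     }))
    taken <- logical(length(truths))
    pairs <- list()
    for (i in order(vapply(preds, `[[`, numeric(1), "score"), decreasing = TRUE)) {
      cand <- which(!taken & iou_mat[i, ] >= iou_min)
      if (!length(cand)) next
      j <- cand[which.max(iou_mat[i, cand])]
      taken[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(i, j, iou_mat[i, j])
    }
    do.call(rbind, pairs)
  }
  for (s in 1:10) {
    withr::with_seed(s, {
      preds <- lapply(random_masks(6, c(48, 48), seed = s), function(m)
        gland_instance(m, "normal", runif(1)))
      truths <- lapply(random_masks(5, c(48, 48), seed = s + 100), function(m)
        gland_instance(m, "normal", 1))
    })
    got <- match_instances(preds, truths, iou_min = 0.3)
    want <- greedy_oracle(preds, truths, 0.3)
    if (is.null(want)) {
      expect_identical(nrow(got$pairs), 0L)
    } else {
      expect_equal(unname(as.matrix(got$pairs[order(got$pairs$pred), ])),
                   unname(want[order(want[, 1]), , drop = FALSE]))
    }
  }
})

test_that("detection confusion routes matches, misses and false positives", {
  shape <- c(64, 64)
  truths <- lapply(random_masks(3, shape, seed = 5), function(m)
    gland_instance(m, "cancer", 1))
  # perfect predictions -> diagonal
  m <- match_instances(truths, truths)
  cm <- detection_confusion(m, truths, truths)
  expect_identical(cm["cancer", "cancer"], 3L)
  expect_identical(sum(cm) - sum(diag(cm)), 0L)

  # all predictions dropped -> everything in the stroma column
  m0 <- match_instances(list(), truths)
  cm0 <- detection_confusion(m0, list(), truths)
  expect_identical(cm0["cancer", "stroma"], 3L)
  expect_identical(sum(cm0), 3L)
})

test_that("reference detection counts reproduce the published report table", {
  cm <- reference_counts("detection")
  expect_identical(as.integer(rowSums(cm)), c(116L, 251L, 9L))
  expect_identical(sum(cm), 376L)
  r <- report(cm)
  pc <- r$per_class
  expect_equal(round(pc$precision[pc$class == "cancer"], 2), 0.95)
  expect_equal(round(pc$recall[pc$class == "cancer"], 2), 0.82)
  expect_equal(round(pc$f1[pc$class == "cancer"], 2), 0.88)
  expect_equal(round(pc$precision[pc$class == "normal"], 2), 0.98)
  expect_equal(round(pc$recall[pc$class == "normal"], 2), 0.99)
  expect_equal(pc$precision[pc$class == "stroma"], 0)
  expect_equal(round(r$accuracy, 2), 0.91)
  expect_equal(round(r$weighted_avg[["f1"]], 2), 0.93)
  expect_equal(round(r$macro_avg[["precision"]], 2), 0.64)
})

test_that("classification report drops unmatched territory and hits 99.71%", {
  cm <- reference_counts("classification")
  expect_identical(as.integer(rowSums(cm)), c(96L, 248L))
  expect_identical(sum(cm), 344L)
  r <- report(cm)
  expect_equal(round(100 * r$accuracy, 2), 99.71)
  pc <- r$per_class
  expect_equal(round(pc$precision[pc$class == "cancer"], 2), 1.00)
  expect_equal(round(pc$recall[pc$class == "cancer"], 2), 0.99)
})

test_that("core-diagnosis report reproduces the published table", {
  r <- report(reference_counts("cores"))
  pc <- r$per_class
  expect_equal(round(pc$precision[pc$class == "cancer"], 2), 0.93)
  expect_equal(round(pc$recall[pc$class == "cancer"], 2), 1.00)
  expect_equal(round(pc$recall[pc$class == "normal"], 2), 0.94)
  expect_equal(round(pc$f1, 2), c(0.97, 0.97))
  expect_equal(round(r$accuracy, 2), 0.97)
})

test_that("report metrics: identity matrix scores 1, permutation invariant,
           weighted F1 matches its definition", {
  idm <- diag(5L) * 7L
  dimnames(idm) <- list(actual = letters[1:5], predicted = letters[1:5])
  r <- report(idm)
  expect_true(all(r$per_class$precision == 1 & r$per_class$recall == 1 &
                    r$per_class$f1 == 1))
  expect_identical(r$accuracy, 1)

  cm <- reference_counts("detection")
  perm <- c(2, 3, 1)
  r1 <- report(cm); r2 <- report(cm[perm, perm])
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(sort(r1$per_class$f1), sort(r2$per_class$f1))
  expect_equal(r1$weighted_avg, r2$weighted_avg)
  expect_equal(r1$weighted_avg[["f1"]],
               sum(r1$per_class$support * r1$per_class$f1) /
                 sum(r1$per_class$support))
  expect_error(report(matrix(0, 2, 2)), class = "slimscreen_parameter_error")
})

test_that("confidence sweep is monotone and saturates for an oracle detector", {
  cores <- fixture_core_set(4, shape = c(256L, 256L), seed_base = 9400L)
  phases <- lapply(cores, `[[`, "phase")
  truths <- lapply(cores, `[[`, "truth")
  sw <- confidence_sweep(classical_params(), phases, truths)
  expect_identical(sw$threshold, c(0.7, 0.8, 0.9))
  expect_true(all(diff(sw$detected_fraction) <= 0))

  # oracle detector on its own core: fraction 1 at every threshold
  one <- confidence_sweep(oracle_detector(truths[[1]]), phases[1], truths[1])
  expect_true(all(one$detected_fraction == 1))

  # threshold above every score: nothing detected
  none <- confidence_sweep(classical_params(), phases, truths, thresholds = 1)
  expect_true(all(none$detected == 0))
})

test_that("trapezoidal AUC equals pairwise concordance and handles edge cases", {
  concordance <- function(s, y) {
    pos <- s[y]; neg <- s[!y]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  for (s in 1:8) {
    withr::with_seed(s, {
      n <- sample(20:200, 1)
      scores <- round(rnorm(n), 1)  # rounded: plenty of ties
      labels <- runif(n) < plogis(scores)
    })
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels), concordance(scores, labels))
  }
  expect_identical(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "slimscreen_parameter_error")
})

test_that("label-independent scores give AUC near one half", {
  aucs <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      scores <- rnorm(2000)
      labels <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
    })
    roc_auc(scores, labels)
  }, numeric(1))
  se <- sqrt(2001 / (12 * 1000 * 1000))  # Mann-Whitney null sd, n1 ~ n2 ~ 1000
  expect_true(all(abs(aucs - 0.5) < 4 * se))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})
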