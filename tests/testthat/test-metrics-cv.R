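test_that("AUROC handles perfect, inverted and tied rankings", {
  expect_identical(auroc(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1)
  expect_identical(auroc(c(.9, .8, .2, .1), c(0, 0, 1, 1)), 0)
  expect_identical(auroc(c(.5, .5, .5, .5), c(1, 0, 1, 0)), 0.5)
  expect_error(auroc(c(.1, .2), c(1, 1)), "single class")
})

test_that("AUROC equals the brute-force pairwise rank oracle", {
  withr::with_seed(20, {
    for (rep in 1:10) {
      n <- sample(10:40, 1)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      scores <- round(runif(n), sample(c(1, 2, 8), 1))   # force some ties
      expect_equal(auroc(scores, labels), auroc_brute(scores, labels))
    }
  })
})

test_that("AUROC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(21, {
    scores <- runif(200)
    labels <- rbinom(200, 1, 0.4)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, labels), ref)
})

test_that("random scores on balanced labels sit at the rank-statistic null", {
  withr::with_seed(22, {
    scores <- runif(10000)
    labels <- rep(c(0, 1), 5000)
  })
  a <- auroc(scores, labels)
  expect_gt(a, 0.47); expect_lt(a, 0.53)
})

test_that("AUPRC reduces to prevalence for random scores and 1 for perfect", {
  expect_equal(auprc(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1)
  withr::with_seed(23, {
    scores <- runif(5000)
    labels <- rbinom(5000, 1, 0.3)
  })
  expect_lt(abs(auprc(scores, labels) - mean(labels)), 0.03)
})

test_that("the six-metric table is computed at the 0.5 threshold", {
  m <- compute_metrics(c(.9, .8, .6, .4, .2, .1), c(1, 1, 0, 1, 0, 0))
  expect_named(m, c("auroc", "auprc", "accuracy", "sensitivity",
                    "specificity", "f1"))
  # predictions at 0.5: (1,1,1,0,0,0) vs labels (1,1,0,1,0,0)
  expect_equal(unname(m["accuracy"]), 4 / 6)
  expect_equal(unname(m["sensitivity"]), 2 / 3)
  expect_equal(unname(m["specificity"]), 2 / 3)
  expect_equal(unname(m["f1"]), 2 / 3)
})

test_that("stratified folds are disjoint, exhaustive and balanced", {
  withr::with_seed(24, labels <- sample(c(rep(1, 106), rep(0, 153))))
  fold <- stratified_folds(labels, 5, seed = 1)
  sizes <- sort(tabulate(fold, 5), decreasing = TRUE)
  expect_identical(sizes, c(52L, 52L, 52L, 52L, 51L))   # 259 = 4x52 + 51
  # per-class balance within one patient
  pos <- tabulate(fold[labels == 1], 5)
  expect_lte(diff(range(pos)), 1)
  expect_identical(sort(unique(fold)), 1:5)
  expect_error(stratified_folds(labels, 300), "k <= n")
})

test_that("cross-validation partitions exactly, avoids leakage, and reproduces", {
  co <- small_cohort(n = 45, seed = 8, tiles = 1)
  cfg <- quick_cfg(c("C", "P"), epochs = 2, seed = 11)
  expect_identical(formals(cross_validate)$k, 5)        # protocol default
  cv <- cross_validate(co, k = 3, config = cfg)
  tested <- unlist(lapply(cv$folds, `[[`, "patient_ids"))
  expect_setequal(tested, co$patients$patient_id)       # exhaustive
  expect_identical(anyDuplicated(tested), 0L)           # disjoint
  # leakage guard: each fold's mappers were fitted on its training ids only
  for (f in cv$folds) {
    expect_setequal(f$mappers$C$fit_ids,
                    setdiff(co$patients$patient_id, f$patient_ids))
  }
  cv2 <- cross_validate(co, k = 3, config = cfg)
  expect_identical(cv$metrics, cv2$metrics)             # seeded end-to-end
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_error(cross_validate(co, k = 60, config = cfg), "k")
})

test_that("subgroup reporting pools out-of-fold scores per stratum", {
  co <- small_cohort(n = 45, seed = 9, tiles = 1)
  cfg <- quick_cfg("C", epochs = 2, seed = 12)
  cv <- cross_validate(co, k = 3, config = cfg)
  groups <- setNames(rep(c("a", "b"), length.out = 45),
                     co$patients$patient_id)
  sg <- subgroup_metrics(cv, groups)
  expect_identical(rownames(sg), c("a", "b"))
  expect_true(all(is.finite(sg[, "auroc"])))
})
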