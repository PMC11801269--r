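linear_f <- function(w) {
  function(x) list(value = sum(w * x), grad = w)
}

test_that("IG on a linear model is exact at any step count", {
  withr::with_seed(30, {
    w <- rnorm(12)
    x <- rnorm(12)
  })
  for (steps in c(1, 3, 50)) {
    ig <- integrated_gradients(linear_f(w), x, rep(0, 12), steps)
    expect_equal(ig$attributions, w * x, tolerance = 1e-12)
    expect_lt(ig$completeness_gap, 1e-10)
  }
})

test_that("IG vanishes when the sample equals the baseline", {
  withr::with_seed(31, x <- rnorm(6))
  f <- function(z) list(value = sum(tanh(z)), grad = 1 / cosh(z)^2)
  ig <- integrated_gradients(f, x, x, 25)
  expect_true(all(ig$attributions == 0))
})

test_that("IG completeness converges to the ten-times-finer Riemann oracle", {
  withr::with_seed(32, {
    W <- matrix(rnorm(6 * 4), 6, 4)
    v <- rnorm(4)
    x <- rnorm(6)
  })
  f <- function(z) {
    h <- tanh(drop(z %*% W))
    list(value = sum(v * h), grad = drop(W %*% (v * (1 - h^2))))
  }
  ig <- integrated_gradients(f, x, rep(0, 6), 30)
  oracle <- integrated_gradients(f, x, rep(0, 6), 300)
  expect_equal(ig$attributions, oracle$attributions, tolerance = 0.02)
  expect_lt(oracle$completeness_gap /
              abs(oracle$value - oracle$baseline_value), 0.01)
})

test_that("features fixed at the baseline receive zero attribution", {
  withr::with_seed(33, {
    w <- rnorm(5)
    x <- rnorm(5)
    b <- rnorm(5)
  })
  x[3] <- b[3]
  ig <- integrated_gradients(linear_f(w), x, b, 20)
  expect_identical(ig$attributions[3], 0)
})

test_that("model attribution reports cover modalities and satisfy completeness", {
  co <- small_cohort(n = 30, seed = 10, tiles = 1)
  m <- flex_train(co, quick_cfg(c("C", "P", "M", "I"), epochs = 3, seed = 13))
  rep_ <- attribute_patients(m, co, co$patients$patient_id[1:4], steps = 50)
  mi <- modal_importance(rep_)
  per <- mi$per_patient
  expect_identical(nrow(per), 4L * 4L)            # four scores per patient
  expect_true(all(per$score >= 0))
  for (ent in rep_$patients) {
    total <- sum(unlist(ent$tabular)) + ent$image$total
    expect_lt(abs(total - (ent$value - ent$baseline_value)),
              0.05 * max(abs(ent$value - ent$baseline_value), 0.01) + 1e-3)
  }
})

test_that("feature ranking is median-based with stable name tie-breaks", {
  rep_ <- structure(list(patients = list(
    a = list(label = 1, tabular = list(P = c(x = 0.2, y = -0.1, z = 0.2))),
    b = list(label = 0, tabular = list(P = c(x = 0.4, y = -0.1, z = 0.4)))
  )), class = "attribution_report")
  rk <- rank_features(rep_, "P")
  expect_identical(rk$feature, c("x", "z", "y"))   # |median| then name
  single <- structure(list(patients = rep_$patients["a"]),
                      class = "attribution_report")
  rk1 <- rank_features(single, "P")
  expect_identical(rk1$feature, c("x", "z", "y"))  # one patient: own order
  expect_identical(nrow(rk), 3L)
})

test_that("SCDA heat maps equal an independent brute-force pipeline", {
  withr::with_seed(34, {
    for (rep in 1:6) {
      h <- sample(3:7, 1); w <- sample(3:7, 1); ch <- sample(1:3, 1)
      fmap <- array(rnorm(h * w * ch), c(h, w, ch))
      S <- apply(fmap, c(1, 2), sum)
      mask <- flexfuse:::largest_component(S > mean(S))
      oracle <- scda_brute(fmap)
      expect_equal(S, oracle$S)
      expect_identical(mask, oracle$mask)
      expect_true(all(S[mask] > mean(S)))          # mask within threshold set
    }
  })
})

test_that("degenerate and hot-block maps threshold as specified", {
  flat <- matrix(1, 4, 4)
  expect_true(all(!flexfuse:::largest_component(flat > mean(flat))))
  hot <- matrix(0, 6, 6); hot[2:3, 4:5] <- 5
  mask <- flexfuse:::largest_component(hot > mean(hot))
  expect_identical(which(mask), which(hot > 0))
})

test_that("heat maps upsample to tile resolution and render to PNG", {
  co <- small_cohort(n = 16, seed = 11, tiles = 1, lesion = 1)
  m <- flex_train(co, quick_cfg("I", epochs = 2, seed = 14))
  tile <- co$images[[co$patients$patient_id[1]]]$tiles[[1]]
  hm <- scda_heatmap(m, tile)
  expect_identical(dim(hm$heat), dim(tile)[1:2])
  expect_identical(dim(hm$mask_full), dim(tile)[1:2])
  path <- withr::local_tempfile(fileext = ".png")
  render_heatmap(hm, path)
  expect_true(file.exists(path))
  img <- png::readPNG(path)
  expect_identical(dim(img)[1:2], dim(tile)[1:2])
})
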