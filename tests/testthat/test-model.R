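test_that("training is bitwise reproducible and refuses degenerate labels", {
  co <- small_cohort(n = 24, seed = 1, tiles = 1)
  cfg <- quick_cfg(c("C", "P"), epochs = 3, seed = 9)
  m1 <- flex_train(co, cfg)
  m2 <- flex_train(co, cfg)
  expect_identical(flexfuse:::tree_max_abs_diff(m1$params, m2$params), 0)
  expect_identical(flex_predict(m1, co), flex_predict(m2, co))

  one_class <- co
  one_class$patients$label <- 1L
  expect_error(flex_train(one_class, cfg), "single class")
})

test_that("zero learning rate leaves every parameter untouched", {
  co <- small_cohort(n = 20, seed = 2, tiles = 1)
  m0 <- flex_train(co, quick_cfg("C", epochs = 1, seed = 4, lr = 0))
  m3 <- flex_train(co, quick_cfg("C", epochs = 3, seed = 4, lr = 0))
  expect_identical(flexfuse:::tree_max_abs_diff(m0$params, m3$params), 0)
})

test_that("a tiny cohort is overfit: loss falls from epoch 1 to epoch 20", {
  co <- small_cohort(n = 16, seed = 3, tiles = 1, lesion = 1)
  cfg <- quick_cfg(c("C", "P", "M", "I"), epochs = 20, seed = 5)
  m <- flex_train(co, cfg)
  expect_lt(tail(m$history$bce, 1), m$history$bce[1])
})

test_that("every fusion method trains end-to-end with gradient in every encoder", {
  co <- small_cohort(n = 20, seed = 4, tiles = 1)
  for (fu in c("summation", "multiplication", "gating", "concatenation")) {
    cfg <- quick_cfg(c("C", "P", "M", "I"), epochs = 1, seed = 6, fusion = fu)
    m1 <- flex_train(co, cfg)
    cfg2 <- cfg; cfg2$epochs <- 2
    m2 <- flex_train(co, cfg2)
    # one more epoch moves tabular encodings and conv weights alike
    expect_gt(max(abs(m1$params$enc$C$E - m2$params$enc$C$E)), 0)
    expect_gt(max(abs(m1$params$enc$M$E - m2$params$enc$M$E)), 0)
    expect_gt(max(abs(m1$params$img$layers[[1]]$W -
                        m2$params$img$layers[[1]]$W)), 0)
  }
})

test_that("all fifteen modality subsets build and train", {
  co <- small_cohort(n = 20, seed = 5, tiles = 1)
  subsets <- unlist(lapply(1:4, function(k)
    combn(c("C", "P", "M", "I"), k, simplify = FALSE)), recursive = FALSE)
  expect_length(subsets, 15)
  for (mods in subsets) {
    m <- flex_train(co, quick_cfg(mods, epochs = 1, seed = 7))
    p <- flex_predict(m, co)
    expect_length(p, 20)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("missing modalities route through Meta and zero replacement differs", {
  co <- small_cohort(n = 30, seed = 6, tiles = 1,
                     modalities_missing = c(P = 0.2))
  cfg <- quick_cfg(c("C", "P", "M"), epochs = 3, seed = 8)
  m <- flex_train(co, cfg)
  pm <- flex_predict(m, co, impute = "meta")
  pz <- flex_predict(m, co, impute = "zero")
  miss <- !co$patients$has_P
  expect_gt(max(abs(pm[miss] - pz[miss])), 0)   # strategies actually differ
  expect_equal(pm[!miss], pz[!miss])            # complete rows unaffected
})

test_that("checkpoints reload to an identical model", {
  co <- small_cohort(n = 16, seed = 7, tiles = 1)
  m <- flex_train(co, quick_cfg(c("C", "P", "I"), epochs = 2, seed = 10))
  path <- withr::local_tempfile(fileext = ".json")
  save_flex_model(m, path)
  back <- load_flex_model(path)
  expect_equal(flex_predict(back, co), flex_predict(m, co),
               tolerance = 1e-12)
  expect_identical(back$config$modalities, m$config$modalities)
})
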