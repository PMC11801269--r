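make_reps <- function(seed = 1, d = 32) {
  withr::with_seed(seed, list(C = runif(d), P = runif(d), M = runif(d),
                              I = runif(d)))
}

test_that("concatenation stacks four 32-dim representations into 128", {
  cfg <- fusion_config("concatenation")
  f <- fuse(make_reps(), cfg)
  expect_length(f, 128)
})

test_that("an all-zero representation annihilates multiplication fusion", {
  cfg <- fusion_config("multiplication")
  reps <- make_reps()
  reps$M <- rep(0, 32)
  expect_true(all(fuse(reps, cfg) == 0))
})

test_that("summation is modality-order invariant; concatenation is not", {
  reps <- make_reps(2)
  s1 <- fuse(reps, fusion_config("summation"))
  s2 <- fuse(rev(reps), fusion_config("summation"))
  expect_equal(s1, s2)
  c1 <- fuse(reps, fusion_config("concatenation"))
  # fixed C, P, M, I order: reversing the input list must not change output
  expect_equal(c1, fuse(rev(reps), fusion_config("concatenation")))
  # but the concatenated vector itself distinguishes the blocks
  expect_false(isTRUE(all.equal(c1[1:32], c1[33:64])))
})

test_that("gating weights are sigmoidal and gradients stay well defined", {
  cfg <- fusion_config("gating")
  withr::with_seed(3, params <- flexfuse:::init_fusion(cfg))
  reps <- lapply(make_reps(4), function(r) matrix(r, 1))
  fc <- flexfuse:::fuse_forward(reps, cfg, params)
  g <- fc$gate_cache$y
  expect_true(all(g > 0 & g < 1))
  expect_length(fc$fused, 32)
})

test_that("mismatched representation widths fail for elementwise methods", {
  reps <- make_reps(5)
  reps$P <- runif(16)
  expect_error(fuse(reps, fusion_config("summation")), "equal d_rep")
})

test_that("the classifier is exactly two layers with sigmoid output", {
  cfg <- fusion_config("concatenation", hidden = 64)
  withr::with_seed(6, params <- flexfuse:::init_fusion(cfg))
  mats <- Filter(is.matrix, unlist(params$clf, recursive = FALSE))
  expect_length(mats, 2)                     # two weight matrices
  x <- matrix(rnorm(5 * 128, sd = 10), 5, 128)
  p <- classify(x, params$clf)
  expect_true(all(p > 0 & p < 1))
  # zero-initialized output layer: probability one half everywhere
  expect_true(all(p == 0.5))
  expect_error(classify(matrix(0, 1, 50), params$clf), "width")
})

test_that("meta imputation matches the target dimension and rejects double missingness", {
  cfg <- fusion_config("concatenation", d_rep = 32)
  withr::with_seed(7, meta <- flexfuse:::init_meta(cfg))
  reps <- make_reps(8)
  imp <- impute_modality(reps[c("C", "P", "M")], "I", meta, cfg)
  expect_length(imp, 32)
  expect_error(impute_modality(reps[c("C", "P")], "I", meta, cfg),
               "unsupported case")
})
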