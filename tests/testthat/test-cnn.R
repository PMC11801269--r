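test_that("convolution kernel matches a direct nested-loop oracle", {
  withr::with_seed(10, {
    for (case in list(list(H = 7, C = 2, K = 3, k = 3, s = 1, p = 1),
                      list(H = 8, C = 3, K = 4, k = 3, s = 2, p = 1),
                      list(H = 9, C = 1, K = 2, k = 1, s = 1, p = 0))) {
      x <- array(rnorm(case$H^2 * case$C * 2), c(case$H, case$H, case$C, 2))
      w <- array(rnorm(case$k^2 * case$C * case$K),
                 c(case$k, case$k, case$C, case$K))
      b <- rnorm(case$K)
      y <- flexfuse:::.conv2d_forward(x, w, b, case$s, case$p)
      for (n in 1:2)
        expect_equal(array(y[, , , n], dim(y)[1:3]),
                     conv_brute(array(x[, , , n], dim(x)[1:3]), w, b,
                                case$s, case$p))
    }
  })
})

test_that("convolution backward matches numerical finite differences", {
  withr::with_seed(11, {
    x <- array(rnorm(5 * 5 * 2 * 1), c(5, 5, 2, 1))
    w <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
    b <- rnorm(2)
  })
  loss <- function(x, w, b) sum(flexfuse:::.conv2d_forward(x, w, b, 1, 1)^2)
  y <- flexfuse:::.conv2d_forward(x, w, b, 1, 1)
  g <- flexfuse:::.conv2d_backward(x, w, 2 * y, 1, 1)
  eps <- 1e-6
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + eps
    expect_equal(g$dx[i], (loss(xp, w, b) - loss(x, w, b)) / eps,
                 tolerance = 1e-3)
  }
  for (i in sample(length(w), 5)) {
    wp <- w; wp[i] <- wp[i] + eps
    expect_equal(g$dw[i], (loss(x, wp, b) - loss(x, w, b)) / eps,
                 tolerance = 1e-3)
  }
})

test_that("tile encoding is deterministic, pooled, and dimension-stable", {
  cfg <- backbone_config("tiny_cnn", d_rep = 32)
  withr::with_seed(12, {
    params <- init_backbone(cfg)
    tile <- array(runif(32 * 32 * 3), c(32, 32, 3))
  })
  one <- encode_tiles(list(tile), cfg, params)
  expect_length(one, 32)
  # duplicating a tile leaves the mean-pooled representation unchanged
  many <- encode_tiles(list(tile, tile, tile), cfg, params)
  expect_equal(many, one)
  # tile order never matters
  withr::with_seed(13, tiles <- lapply(1:4, function(i)
    array(runif(32 * 32 * 3), c(32, 32, 3))))
  expect_equal(encode_tiles(tiles, cfg, params),
               encode_tiles(rev(tiles), cfg, params))
  expect_error(encode_tiles(list(), cfg, params), "Meta")
})

test_that("every backbone architecture honours the representation contract", {
  withr::with_seed(14, tile <- array(runif(64 * 64 * 3), c(64, 64, 3)))
  for (arch in c("tiny_cnn", "resnet18", "resnet34", "resnet50", "vgg16")) {
    cfg <- backbone_config(arch, d_rep = 32)
    withr::with_seed(15, params <- init_backbone(cfg))
    r <- encode_tiles(list(tile), cfg, params)
    expect_length(r, 32)
    expect_identical(r, encode_tiles(list(tile), cfg, params))
    fm <- feature_map(tile, cfg, params)
    expect_identical(length(dim(fm)), 3L)
    expect_true(all(dim(fm)[1:2] >= 1))
  }
})

test_that("tiny_cnn keeps a spatial tap point on 64x64 tiles", {
  cfg <- backbone_config("tiny_cnn")
  withr::with_seed(16, params <- init_backbone(cfg))
  tile <- array(0.5, c(64, 64, 3))
  fm <- feature_map(tile, cfg, params)
  expect_true(all(dim(fm)[1:2] >= 4))
  # eval mode: identical maps for identical tiles
  expect_identical(fm, feature_map(tile, cfg, params))
})

test_that("a bias-free backbone maps an all-zero tile to an all-zero tap", {
  cfg <- backbone_config("tiny_cnn")
  withr::with_seed(17, params <- init_backbone(cfg))
  params$layers <- lapply(params$layers, function(nd) {
    if (nd$type == "conv") nd$b[] <- 0
    nd
  })
  fm <- feature_map(array(0, c(16, 16, 3)), cfg, params)
  expect_true(all(fm == 0))
})

test_that("attention pooling weights tiles and still projects to d_rep", {
  cfg <- backbone_config("tiny_cnn", pooling = "attention", d_rep = 16)
  withr::with_seed(18, {
    params <- init_backbone(cfg)
    params$attn_q$q <- rnorm(length(params$attn_q$q))
    tiles <- lapply(1:3, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  })
  r <- encode_tiles(tiles, cfg, params)
  expect_length(r, 16)
  expect_equal(r, encode_tiles(rev(tiles), cfg, params)) # softmax over tiles
})
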