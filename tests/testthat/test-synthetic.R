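test_that("identical seeds reproduce the cohort bitwise", {
  cfg <- sim_config(n_patients = 25, tile_size = 16, tiles_per_patient = 2,
                    seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$tables, b$tables)
  expect_identical(a$images[["PT0001"]]$tiles, b$images[["PT0001"]]$tiles)
})

test_that("marginals match the stated distributional structure", {
  co <- generate_cohort(sim_config(n_patients = 5000, tiles_per_patient = 1,
                                   tile_size = 8, lesion_signal = 0,
                                   seed = 11))
  truth <- attr(co, "truth")
  # binary clinical features track their generating Bernoulli p
  p_hat <- colMeans(co$tables$C$values[, seq_along(truth$features$C$bernoulli_p)])
  expect_true(all(abs(p_hat - truth$features$C$bernoulli_p) < 0.03))
  # long-tailed omics features: positive sample skewness above 1
  skew <- apply(co$tables$P$values, 2, function(x)
    mean((x - mean(x))^3) / sd(x)^3)
  expect_true(all(skew > 1))
  # prevalence near the calibrated 106/259 target
  expect_lt(abs(mean(co$patients$label) - 0.41), 0.05)
})

test_that("realized modality missingness matches the configured rate", {
  co <- generate_cohort(sim_config(n_patients = 1000, tiles_per_patient = 1,
                                   tile_size = 8,
                                   missing_rate = c(P = 0.2, I = 0.1),
                                   seed = 5))
  expect_lt(abs(mean(!co$patients$has_P) - 0.2), 0.05)
  expect_lt(abs(mean(!co$patients$has_I) - 0.1), 0.05)
  # nobody loses two modalities
  miss <- rowSums(!as.matrix(co$patients[, c("has_C", "has_P", "has_M", "has_I")]))
  expect_lte(max(miss), 1)
})

test_that("null effects give chance-level signal; planted effects are learnable", {
  # standalone logistic-fit oracle, independent of the package's model
  co0 <- generate_cohort(sim_config(n_patients = 2000, effect_size = 0,
                                    tiles_per_patient = 1, tile_size = 8,
                                    lesion_signal = 0, seed = 12))
  X0 <- cbind(co0$tables$C$values, co0$tables$P$values, co0$tables$M$values)
  y0 <- co0$patients$label
  f0 <- suppressWarnings(glm(y0[1:1000] ~ ., data = as.data.frame(X0[1:1000, ]),
                             family = binomial))
  p0 <- predict(f0, newdata = as.data.frame(X0[1001:2000, ]))
  expect_gt(auroc(p0, y0[1001:2000]), 0.45)
  expect_lt(auroc(p0, y0[1001:2000]), 0.55)

  co1 <- generate_cohort(sim_config(n_patients = 2000,
                                    informative = c(C = 5, P = 0, M = 0),
                                    effect_size = c(C = 1, P = 0, M = 0),
                                    tiles_per_patient = 1, tile_size = 8,
                                    lesion_signal = 0, seed = 11))
  X1 <- co1$tables$C$values
  y1 <- co1$patients$label
  f1 <- suppressWarnings(glm(y1[1:1000] ~ ., data = as.data.frame(X1[1:1000, ]),
                             family = binomial))
  p1 <- predict(f1, newdata = as.data.frame(X1[1001:2000, ]))
  expect_gt(auroc(p1, y1[1001:2000]), 0.80)
})

test_that("write -> load round trip reproduces the cohort through the real readers", {
  co <- small_cohort(n = 10, seed = 3, tiles = 2)
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(any(grepl("labels.csv", files)))
  lab <- read.csv(file.path(dir, "labels.csv"))
  expect_identical(nrow(lab), 10L)
  back <- load_cohort(dir)
  expect_identical(back$patients, co$patients)
  expect_equal(back$tables$P$values, co$tables$P$values)
  # PNG tiles are 8-bit; round trip is exact at that quantization
  expect_equal(back$images[["PT0001"]]$tiles[[1]],
               co$images[["PT0001"]]$tiles[[1]], tolerance = 1 / 254)
  expect_identical(attr(back, "truth")$features$P$informative,
                   attr(co, "truth")$features$P$informative)
  # refuses to clobber an existing cohort unless forced
  expect_error(write_cohort(co, dir), "force")
  expect_silent(write_cohort(co, dir, force = TRUE))
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_patients = 0), "degenerate")
  expect_error(sim_config(informative = c(C = 99)), "informative")
  expect_error(sim_config(lesion_signal = 2), "rates")
})
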