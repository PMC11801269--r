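test_that("bucket boundaries are the empirical quantiles", {
  tb <- feature_table("P", sprintf("p%03d", 1:100), "f", matrix(1:100, 100, 1))
  hm <- fit_hash_mapper(tb, n_buckets = 4)
  expect_equal(hm$boundaries$f,
               unname(quantile(1:100, c(.25, .5, .75))))   # 25.75, 50.5, 75.25
})

test_that("constant features collapse to a single midpoint and B=2 splits at the median", {
  tb <- feature_table("C", c("a", "b", "c"), c("k", "s"),
                      cbind(c(7, 7, 7), c(1, 2, 3)))
  hm <- fit_hash_mapper(tb, 8)
  mapped <- apply_hash_map(hm, tb)
  expect_true(all(mapped$values[, "k"] == 0.5))

  tb2 <- feature_table("C", sprintf("p%d", 1:10), "x", matrix(1:10, 10, 1))
  hm2 <- fit_hash_mapper(tb2, 2)
  m2 <- apply_hash_map(hm2, tb2)$values[, "x"]
  expect_setequal(unique(m2), c(0.25, 0.75))
  expect_true(all(m2[1:5] == 0.25) && all(m2[6:10] == 0.75))
})

test_that("out-of-range values clamp to the extreme buckets", {
  tb <- feature_table("M", sprintf("p%d", 1:50), "x", matrix(rnorm(50), 50, 1))
  hm <- fit_hash_mapper(tb, 16)
  probe <- feature_table("M", c("lo", "hi"), "x",
                         matrix(c(-1e9, 1e9), 2, 1))
  m <- apply_hash_map(hm, probe)$values[, "x"]
  expect_equal(unname(m), c(0.5 / 16, 15.5 / 16))
})

test_that("mapping is monotone and agrees with a brute-force bucket oracle", {
  withr::with_seed(8, {
    for (rep in 1:5) {
      x <- c(rlnorm(40), rnorm(20))
      tb <- feature_table("P", sprintf("p%02d", seq_along(x)), "x",
                          matrix(x, ncol = 1))
      B <- sample(c(4, 8, 16), 1)
      hm <- fit_hash_mapper(tb, B)
      m <- apply_hash_map(hm, tb)$values[, "x"]
      # brute-force bucket assignment: count boundaries strictly below / at x
      b <- hm$boundaries$x
      oracle <- vapply(x, function(v) (sum(b <= v) + 0.5) / (length(b) + 1),
                       numeric(1))
      expect_equal(unname(m), oracle)
      expect_true(all(diff(m[order(x)]) >= 0))        # monotone per feature
    }
  })
})

test_that("missing cells map to the reserved code, never a midpoint", {
  tb <- feature_table("P", c("a", "b", "c"), "x",
                      matrix(c(1, NA, 3), 3, 1))
  hm <- fit_hash_mapper(tb, 4)
  m <- apply_hash_map(hm, tb)$values[, "x"]
  expect_identical(unname(m[2]), missing_code())
  expect_true(all(m[c(1, 3)] >= 0 & m[c(1, 3)] <= 1))
})

test_that("hash mapping is idempotent on already-mapped midpoints", {
  # equal-probability midpoints refit to themselves: the bucket transform
  # is a projection on its own output
  withr::with_seed(3, x <- rnorm(64))
  tb <- feature_table("C", sprintf("p%02d", 1:64), "x", matrix(x, ncol = 1))
  hm <- fit_hash_mapper(tb, 8)
  m1 <- apply_hash_map(hm, tb)
  hm2 <- fit_hash_mapper(m1, 8)
  m2 <- apply_hash_map(hm2, m1)
  expect_equal(m2$values, m1$values)
})

test_that("feature-set mismatch and all-missing features are errors", {
  tb <- tiny_table(5, 3, "C")
  hm <- fit_hash_mapper(tb, 4)
  other <- tiny_table(5, 4, "C")
  expect_error(apply_hash_map(hm, other), "different feature set")
  vals <- tb$values; vals[, 2] <- NA
  allmiss <- feature_table("C", tb$patient_ids, tb$feature_names, vals)
  expect_error(fit_hash_mapper(allmiss, 4), tb$feature_names[2])
})

test_that("mapper JSON serialization round trips", {
  tb <- tiny_table(20, 4, "M", seed = 5)
  hm <- fit_hash_mapper(tb, 16)
  path <- withr::local_tempfile(fileext = ".json")
  write_hash_mapper(hm, path)
  back <- read_hash_mapper(path)
  expect_equal(back$boundaries, hm$boundaries)
  expect_equal(back$n_buckets, hm$n_buckets)
  expect_equal(apply_hash_map(back, tb)$values, apply_hash_map(hm, tb)$values)
})
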