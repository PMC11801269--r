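test_that("feature table CSV round trip preserves every cell including missing", {
  withr::with_seed(42, {
    vals <- matrix(rnorm(200), 20, 10)
    vals[sample(200, 17)] <- NA
  })
  tb <- feature_table("P", sprintf("PT%02d", 1:20),
                      sprintf("prot_%02d", 1:10), vals)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tb, path)
  back <- load_feature_table(path, "P")
  expect_identical(back$patient_ids, tb$patient_ids)
  expect_identical(back$feature_names, tb$feature_names)
  expect_equal(back$values, tb$values)
  # no imputation at load time: missing-sentinel count equals empty cells
  expect_identical(sum(is.na(back$values)), sum(is.na(vals)))
})

test_that("loader rejects duplicate patients and locates non-numeric cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,a,b", "p1,1,2", "p1,3,4"), path)
  expect_error(load_feature_table(path, "C"), "duplicate patient")
  writeLines(c("patient_id,a,b", "p1,1,2", "p2,x,4"), path)
  expect_error(load_feature_table(path, "C"), "row 2, column 'a'")
  # empty cells are missing, not errors, and never zero-filled
  writeLines(c("patient_id,a,b", "p1,,2", "p2,3,"), path)
  tb <- load_feature_table(path, "C")
  expect_identical(sum(is.na(tb$values)), 2L)
})

test_that("cohort assembly sets presence flags from availability", {
  tc <- tiny_table(4, 2, "C")
  tp <- tiny_table(4, 3, "P")
  labels <- setNames(c(1, 0, 1, 0), tc$patient_ids)
  co <- assemble_cohort(list(tc, tp), labels = labels)
  expect_true(all(co$patients$has_C, co$patients$has_P))
  expect_false(any(co$patients$has_M, co$patients$has_I))

  # one patient lacking proteomics keeps its record with the flag false
  tp3 <- feature_table("P", tp$patient_ids[-2], tp$feature_names,
                       tp$values[-2, , drop = FALSE])
  co3 <- assemble_cohort(list(tc, tp3), labels = labels)
  expect_identical(co3$patients$has_P,
                   co3$patients$patient_id != tc$patient_ids[2])
})

test_that("missing labels are an error naming the patient", {
  tc <- tiny_table(4, 2, "C")
  labels <- setNames(c(1, 0, 1), tc$patient_ids[1:3])
  expect_error(assemble_cohort(list(tc), labels = labels),
               tc$patient_ids[4])
})

test_that("assembly is order-independent up to patient ordering", {
  tc <- tiny_table(6, 3, "C", seed = 7)
  labels <- setNames(rep(c(0, 1), 3), tc$patient_ids)
  perm <- feature_table("C", tc$patient_ids[6:1], tc$feature_names,
                        tc$values[6:1, , drop = FALSE])
  a <- assemble_cohort(list(tc), labels = labels)
  b <- assemble_cohort(list(perm), labels = labels)
  expect_identical(a$patients, b$patients)
  expect_equal(a$tables$C$values[a$patients$patient_id, ],
               b$tables$C$values[b$patients$patient_id, ])
})

test_that("duplicate records keep progression and earlier acquisitions", {
  lab <- data.frame(patient_id = c("p1", "p1", "p2", "p2", "p3"),
                    label = c(0, 1, 0, 0, 1),
                    acquisition_time = c(1, 5, 9, 2, 3))
  out <- deduplicate_patients(lab)
  expect_identical(nrow(out), 3L)
  expect_identical(out$label[out$patient_id == "p1"], 1)   # progression wins
  expect_identical(out$acquisition_time[out$patient_id == "p2"], 2) # earlier
})
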