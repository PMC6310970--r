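test_that("presence filter removes exactly the all-zero features", {
  set.seed(1)
  m <- matrix(rexp(80), 10, 8, dimnames = list(NULL, paste0("f", 1:8)))
  m[, c(2, 5, 7)] <- 0
  ds <- ds_from_matrix(m)
  res <- filter_presence(ds)
  expect_equal(res$report$kept_count, 5)
  expect_setequal(res$report$removed_ids, c("f2", "f5", "f7"))
  expect_true(all(res$report$rule_per_id == "all_zero"))
  expect_equal(ncol(res$dataset$values), 5)
  expect_identical(res$dataset$stage, "filtered")

  # no all-zero columns: unchanged, empty report
  clean <- ds_from_matrix(matrix(rexp(40) + 1, 10, 4))
  res2 <- filter_presence(clean)
  expect_equal(res2$dataset$values, clean$values)
  expect_length(res2$report$removed_ids, 0)
})

test_that("zero-target samples are reported but never dropped", {
  m <- matrix(rexp(40) + 1, 10, 4)
  ds <- expression_dataset(m, target = c(0, rep(1, 8), 0))
  res <- filter_presence(ds)
  expect_equal(res$report$zero_target_samples, c(1L, 10L))
  expect_equal(nrow(res$dataset$values), 10)
})

test_that("low-information filter applies the Q3 and zero-mode rules in order", {
  n <- 100
  set.seed(99)
  cols <- cbind(
    keep_const5 = rep(5, n),                          # Q3=5, mode 5 != 0
    drop_q3     = c(rep(1.5, 80), rep(10, 20)),       # Q3 = 1.5 < 2
    drop_mode   = c(rep(0, 20), rexp(80) + 5),        # mode 0 at 20% > 15%
    keep_ok     = rep(c(3, 8), 50),
    both_rules  = c(rep(0, 80), rep(10, 20))          # Q3 matches first
  )
  ds <- ds_from_matrix(cols, target = rexp(n))
  res <- filter_low_information(ds)
  expect_setequal(res$report$removed_ids, c("drop_q3", "drop_mode", "both_rules"))
  expect_identical(unname(res$report$rule_per_id[["drop_q3"]]), "q3_below_2")
  expect_identical(unname(res$report$rule_per_id[["drop_mode"]]), "zero_mode_frequent")
  # first matching rule wins: Q3(both_rules) = 0 < 2
  expect_identical(unname(res$report$rule_per_id[["both_rules"]]), "q3_below_2")
  expect_equal(res$report$kept_count, 2)
  # hand check of the type-7 quartile on the planted column
  expect_lt(quantile(cols[, "drop_q3"], 0.75, type = 7), 2)
})

test_that("zero mode below the frequency cut is retained", {
  n <- 100
  x <- c(rep(0, 10), rexp(90) + 5)   # mode 0 but only 10% <= 15%
  ds <- ds_from_matrix(cbind(a = x, b = rep(c(3, 9), 50)), target = rexp(n))
  res <- filter_low_information(ds)
  expect_length(res$report$removed_ids, 0)
})

test_that("filters are idempotent and order-invariant", {
  ds <- toy_dataset(n = 120, p = 15, seed = 13, zero_inflation = 0.12,
                    dispersion = 2)
  a1 <- filter_presence(ds)
  a2 <- filter_presence(a1$dataset)
  expect_equal(a2$dataset$values, a1$dataset$values)
  expect_length(a2$report$removed_ids, 0)

  b1 <- filter_low_information(ds)
  b2 <- filter_low_information(b1$dataset)
  expect_equal(b2$dataset$values, b1$dataset$values)
  expect_length(b2$report$removed_ids, 0)

  # all-zero columns satisfy both rules, so composition order cannot matter
  ab <- filter_low_information(filter_presence(ds)$dataset)$dataset
  ba <- filter_presence(filter_low_information(ds)$dataset)$dataset
  expect_identical(colnames(ab$values), colnames(ba$values))
  expect_equal(ab$values, ba$values)
})

test_that("kept + removed always reconciles with the input feature count", {
  for (seed in 1:5) {
    ds <- toy_dataset(n = 120, p = 12, seed = seed, zero_inflation = 0.13,
                      dispersion = 2)
    r <- filter_low_information(ds)$report
    expect_equal(r$kept_count + length(r$removed_ids), r$input_count)
  }
})

test_that("scaling matches the mean-anchored example and min-max endpoints", {
  ds <- ds_from_matrix(cbind(a = c(0, 5, 10), b = c(1, 2, 4)),
                       target = c(2, 4, 6), stage = "filtered")
  eq2 <- scale_dataset(ds, scaling_spec("mean_anchored"))
  expect_equal(unname(eq2$values[, "a"]), c(-1, 0, 1))   # (x - mean)/(max - mean)
  expect_equal(eq2$target, c(0, 0.5, 1))
  mm <- scale_dataset(ds, scaling_spec("minmax"))
  expect_equal(unname(mm$values[, "a"]), c(-1, 0, 1))
  expect_equal(range(mm$values), c(-1, 1))
})

test_that("scaling round-trips through the inverse to 1e-12", {
  ds <- toy_scaled(n = 50, p = 8, seed = 17)
  orig <- toy_dataset(n = 50, p = 8, seed = 17)
  back <- inverse_scale(ds)
  kept <- colnames(ds$values)
  expect_equal(back$values, orig$values[, kept], tolerance = 1e-12)
  expect_equal(back$target, orig$target, tolerance = 1e-12)
})

test_that("degenerate columns are reported by name", {
  ds <- ds_from_matrix(cbind(ok = c(1, 2, 3), flat = c(4, 4, 4)),
                       target = 1:3, stage = "filtered")
  expect_error(scale_dataset(ds), "flat")
})

test_that("collinearity screen flags duplicated and negated features only", {
  set.seed(2)
  m <- matrix(rnorm(5000), 1000, 5, dimnames = list(NULL, paste0("g", 1:5)))
  m <- cbind(m, dup = m[, 1], neg = -m[, 2])
  ds <- expression_dataset(abs(m) + 0.01, target = rnorm(1000),
                           stage = "filtered")
  # build directly with signed values to test the screen itself
  ds$values <- m
  rep <- collinearity_report(ds, r_threshold = 0.95)
  expect_equal(nrow(rep), 2)
  expect_setequal(rep$feature_b, c("dup", "neg"))
  expect_equal(abs(rep$r), c(1, 1), tolerance = 1e-12)
  # independent columns alone: empty
  ds2 <- ds; ds2$values <- m[, 1:5]; ds2$feature_ids <- colnames(m)[1:5]
  expect_equal(nrow(collinearity_report(ds2, 0.95)), 0)
})

test_that("full pipeline advances stages and stores scaling parameters", {
  ds <- toy_dataset(n = 64, p = 10, seed = 23)
  pp <- preprocess(ds, denoise = TRUE)
  expect_identical(pp$dataset$stage, "scaled")
  expect_true(all(pp$dataset$values >= -1 - 1e-9 & pp$dataset$values <= 1 + 1e-9))
  expect_true(all(pp$dataset$target >= 0 & pp$dataset$target <= 1))
  expect_named(pp$scaling, c("method", "feature_min", "feature_max",
                             "feature_mean", "target_min", "target_max"))
  # stage transitions only run forward
  expect_error(filter_presence(pp$dataset), "raw or filtered")
})
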