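test_that("dataset building counts one sample per time point and is deterministic", {
  specs <- sample_waveform_specs(n_profiles = 10, seed = 3)
  ds1 <- build_dataset(specs)
  expect_equal(nrow(ds1$data), 10 * 80)
  expect_equal(nrow(ds1$manifest), 10)
  ds2 <- build_dataset(specs)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(ds1$data, ds2$data)
  expect_error(build_dataset(specs[0, ]), "non-empty")
})

test_that("every feature and label is finite across a seeded corpus sweep", {
  ds <- small_dataset()
  num <- ds$data[, c("q", "dq", "d2q", "kappa", "y_otr", "y_hem")]
  expect_true(all(vapply(num, function(x) all(is.finite(x)), TRUE)))
  expect_true(all(ds$data$y_otr >= 0))
  expect_true(all(ds$data$y_hem >= 0))
  expect_true(all(ds$data$kappa >= 0))
})

test_that("splits are by profile, disjoint, exhaustive and at the requested ratios", {
  specs <- sample_waveform_specs(n_profiles = 100, seed = 5)
  ds <- split_dataset(build_dataset(specs), c(0.7, 0.15, 0.15), seed = 5)
  counts <- table(ds$manifest$split)
  expect_equal(unname(counts[c("train", "val", "test")]), c(70L, 15L, 15L),
               ignore_attr = TRUE)
  # no profile straddles splits
  per_profile <- tapply(ds$data$split, ds$data$profile_id,
                        function(s) length(unique(s)))
  expect_true(all(per_profile == 1))
  ds2 <- split_dataset(build_dataset(specs), c(0.7, 0.15, 0.15), seed = 5)
  expect_identical(ds$manifest$split, ds2$manifest$split)
  expect_error(split_dataset(ds, c(1, 0, 0)), "positive")
  tiny <- build_dataset(sample_waveform_specs(n_profiles = 2, seed = 1))
  expect_error(split_dataset(tiny), "3 profiles")
})

test_that("threshold accuracy computes relative-error fractions and is monotone", {
  expect_equal(threshold_accuracy(c(1, 1.05), c(1, 1), thresholds = 3)$accuracy,
               0.5)
  eq <- threshold_accuracy(1:10, 1:10)
  expect_equal(eq$accuracy, rep(1, 5))
  withr::with_seed(2, {
    truth <- runif(500, 1, 10)
    pred <- truth * (1 + rnorm(500, 0, 0.03))
  })
  acc <- threshold_accuracy(pred, truth)$accuracy
  expect_true(all(diff(acc) >= 0))
  expect_error(threshold_accuracy(1:3, 1:4))
  expect_error(threshold_accuracy(numeric(0), numeric(0)))
})

test_that("a constant-label dataset is learned to near-zero error", {
  ds <- small_dataset()
  ds$data$y_otr <- 1.0
  fit <- train_surrogate(ds, small_surrogate_cfg(lr = 1e-3,
                                                 otr_max_epochs = 400,
                                                 otr_patience = 60), "otr")
  te <- ds$data[ds$data$split == "test", ]
  pred <- suppressWarnings(predict(fit, te)$.pred)
  # "zero" relative to the O(1) label scale; Adam's step-size floor keeps the
  # residual above machine precision
  expect_lt(mean((pred - 1)^2), 1e-3)
})

test_that("training returns the best-validation model and its log", {
  ds <- small_dataset()
  fit <- train_surrogate(ds, small_surrogate_cfg(), "hem")
  expect_lte(min(fit$log$val_loss), fit$log$val_loss[1])
  expect_equal(min(fit$log$val_loss), fit$log$val_loss[fit$best_epoch])
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
})

test_that("surrogate training is reproducible from the seed", {
  ds <- small_dataset()
  cfg <- small_surrogate_cfg(otr_max_epochs = 5, seed = 13)
  f1 <- train_surrogate(ds, cfg, "otr")
  f2 <- train_surrogate(ds, cfg, "otr")
  expect_identical(f1$W, f2$W)
  expect_identical(f1$log, f2$log)
})

test_that("a briefly trained surrogate tracks the oracle on held-out waveform shapes", {
  ds <- small_dataset()
  cfg <- small_surrogate_cfg()
  otr <- train_surrogate(ds, cfg, "otr")
  acc_otr <- surrogate_test_accuracy(otr, ds)
  expect_gt(acc_otr$accuracy[acc_otr$threshold_pct == 5], 0.5)
  expect_true(all(diff(acc_otr$accuracy) >= 0))
})

test_that("out-of-distribution inputs are flagged, never silently extrapolated", {
  ds <- small_dataset()
  fit <- train_surrogate(ds, small_surrogate_cfg(otr_max_epochs = 3), "otr")
  far <- matrix(c(50, 5000, 5e5, 100), nrow = 1,
                dimnames = list(NULL, c("q", "dq", "d2q", "kappa")))
  expect_warning(out <- predict(fit, far), "outside the training")
  expect_true(out$.ood)
  inside <- ds$data[ds$data$split == "train", ][10, ]
  expect_silent(ok <- predict(fit, inside))
  expect_false(ok$.ood)
})

test_that("datasets round-trip through the CSV + JSON export", {
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(nrow(back$data), nrow(ds$data))
  expect_equal(back$data$y_otr, ds$data$y_otr, tolerance = 1e-9)
  expect_equal(back$params$oracle$k_ref, ds$params$oracle$k_ref)
})
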