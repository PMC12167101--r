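test_that("NSA scaling is the exact affine map onto [0, 1]", {
  cfg <- fusion_config()
  expect_equal(scale_nsa(90, cfg), 0)
  expect_equal(scale_nsa(135, cfg), 0.5)
  expect_equal(unscale_nsa(scale_nsa(137.2, cfg), cfg), 137.2,
               tolerance = 1e-9)
  expect_error(scale_nsa(89, cfg), "outside the scale range")
  expect_error(scale_nsa(181, cfg), "outside the scale range")
})

test_that("an 80:20 split of 57 single-hip patients gives 45 train / 12 test", {
  rec <- make_view_noise_records(57, seed = 1)
  fit <- train_fusion(rec, fusion_config(seed = 1, epochs = 5))
  expect_length(fit$split$train, 45)
  expect_length(fit$split$test, 12)
  expect_setequal(c(fit$split$train, fit$split$test), 1:57)

  # patient-level splitting keeps bilateral hips on one side
  rec$patient_id <- rep(sprintf("p%02d", 1:29), length.out = 57)
  fit2 <- train_fusion(rec, fusion_config(seed = 2, epochs = 5))
  train_pat <- rec$patient_id[fit2$split$train]
  test_pat <- rec$patient_id[fit2$split$test]
  expect_length(intersect(train_pat, test_pat), 0)
})

test_that("training is reproducible for a fixed seed", {
  rec <- make_view_noise_records(40, seed = 3)
  f1 <- train_fusion(rec, fusion_config(seed = 11, epochs = 50))
  f2 <- train_fusion(rec, fusion_config(seed = 11, epochs = 50))
  expect_identical(predict(f1), predict(f2))
  f3 <- train_fusion(rec, fusion_config(seed = 12, epochs = 50))
  expect_false(identical(f1$split$test, f3$split$test) &&
                 identical(predict(f1), predict(f3)))
})

test_that("the network learns a two-view target that neither view gives alone", {
  set.seed(5)
  n <- 200
  ap <- runif(n, 115, 155)
  lat <- ap + rnorm(n, 0, 6)
  clin <- 0.5 * (ap + lat) + rnorm(n, 0, 1)
  rec <- data.frame(hip_id = sprintf("h%03d", 1:n), nsa_ap_cv = ap,
                    nsa_lateral_cv = lat, nsa_ap_clinician = clin)
  fit <- train_fusion(rec, fusion_config(seed = 3))
  test <- fit$records[fit$split$test, ]
  fused_mae <- mean(abs(predict(fit) - test$nsa_ap_clinician))
  ap_mae <- mean(abs(test$nsa_ap_cv - test$nsa_ap_clinician))
  expect_lt(fused_mae, ap_mae)
})

test_that("both loss choices converge to <= 1 degree on the identity task", {
  set.seed(9)
  n <- 60
  ap <- runif(n, 115, 160)
  rec <- data.frame(hip_id = sprintf("h%02d", 1:n), nsa_ap_cv = ap,
                    nsa_lateral_cv = ap, nsa_ap_clinician = ap)
  for (loss in c("bce_on_scaled", "mse")) {
    fit <- train_fusion(rec, fusion_config(loss = loss, epochs = 3000,
                                           seed = 2))
    test <- fit$records[fit$split$test, ]
    expect_lt(mean(abs(predict(fit) - test$nsa_ap_clinician)), 1)
  }
})

test_that("predictions are bounded by the scale range and use both features", {
  rec <- make_view_noise_records(30, seed = 7)
  fit <- train_fusion(rec, fusion_config(seed = 4, epochs = 200))
  set.seed(1)
  a <- runif(20, 95, 175); b <- runif(20, 95, 175)
  pred <- predict_fused(fit, a, b)
  expect_true(all(pred >= 90 & pred <= 180))
  # the architecture is not symmetric in its two inputs
  expect_false(isTRUE(all.equal(predict_fused(fit, 130, 150),
                                predict_fused(fit, 150, 130))))
  expect_error(predict_fused(list(), 130, 150), "nsa_fusion")
})

test_that("records outside the scale range are excluded with a warning", {
  rec <- make_view_noise_records(20, seed = 8)
  rec$nsa_ap_clinician[3] <- 85          # valid angle, below the scale range
  expect_warning(fit <- train_fusion(rec, fusion_config(seed = 1,
                                                        epochs = 5)),
                 "excluded")
  expect_equal(nrow(fit$records), 19)
  expect_equal(fit$excluded$hip_id, rec$hip_id[3])
  expect_error(train_fusion(rec[1:3, ], fusion_config()), "at least 5")
})

test_that("with view-dependent noise, fusion beats the AP-only baseline in nearly all replicates", {
  wins <- 0
  for (b in 1:20) {
    rec <- make_view_noise_records(57, seed = 2000 + b)
    rel <- run_reliability(rec, fusion_config(), n_repetitions = 5,
                           base_seed = 100 * b)
    s <- rel$summary
    fused <- s$mean[s$model == "fused" & s$metric == "mae"]
    cv <- s$mean[s$model == "cv_only" & s$metric == "mae"]
    wins <- wins + (fused <= cv)
  }
  expect_gte(wins, 18)
})
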