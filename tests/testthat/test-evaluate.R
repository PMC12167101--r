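test_that("Spearman correlation handles monotone and hand-computed cases", {
  x <- c(1, 3, 5, 8)
  expect_equal(spearman_rs(x, x^3)$rs, 1)
  expect_equal(spearman_rs(x, -x)$rs, -1)
  expect_equal(spearman_rs(c(1, 2, 3, 4), c(1, 3, 2, 4))$rs, 0.8)

  expect_error(spearman_rs(1:4, 1:5), "length mismatch")
  expect_error(spearman_rs(1:2, 2:1), "at least 3")
  expect_error(spearman_rs(rep(1, 5), 1:5), "constant")
})

test_that("spearman_rs matches the textbook formula on distinct-value inputs", {
  set.seed(14)
  for (n in 4:8) {
    for (k in 1:6) {
      x <- sample(100, n)
      y <- sample(100, n)
      got <- spearman_rs(x, y)
      want <- oracle_spearman(x, y)
      expect_equal(got$rs, want$rs, tolerance = 1e-12)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
    }
  }
})

test_that("regression metrics follow their definitions", {
  truth <- c(0, 2, 4, 6)
  ident <- regression_metrics(truth, truth)
  expect_equal(ident, list(r_squared = 1, mae = 0, mse = 0))

  off <- regression_metrics(truth + 1, truth)
  expect_equal(off$mae, 1)
  expect_equal(off$mse, 1)
  expect_equal(off$r_squared, 1 - 4 / 20)   # SS_res 4, SS_tot 20

  flat <- regression_metrics(rep(mean(truth), 4), truth)
  expect_equal(flat$r_squared, 0)

  expect_warning(bad <- regression_metrics(c(1, 2), c(3, 3)), "constant")
  expect_true(is.na(bad$r_squared))
})

test_that("agreement metrics satisfy the Jensen relation mae^2 <= mse", {
  set.seed(15)
  for (k in 1:10) {
    pred <- runif(12, 120, 160)
    truth <- runif(12, 120, 160)
    m <- agreement_metrics(pred, truth)
    expect_lte(m$mae^2, m$mse + 1e-12)
    expect_equal(m$n, 12)
  }
})

test_that("Kruskal-Wallis matches the rank-formula oracle including ties", {
  two <- kruskal_wallis(list(c(1, 2, 3), c(101, 102, 103)))
  want <- oracle_kruskal(list(c(1, 2, 3), c(101, 102, 103)))
  expect_equal(two$H, want$H)            # 27/7 for full separation
  expect_equal(two$H, 27 / 7)

  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)

  ident <- kruskal_wallis(list(c(5, 5), c(5, 5, 5)))
  expect_equal(ident$H, 0)
  expect_equal(ident$p_value, 1)

  set.seed(16)
  for (k in 1:8) {
    g <- list(sample(6, 5, replace = TRUE), sample(6, 4, replace = TRUE),
              sample(6, 6, replace = TRUE))
    got <- kruskal_wallis(g)
    want <- oracle_kruskal(g)
    expect_equal(got$H, want$H, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("the reliability protocol stores one metric tuple per repetition and model", {
  rec <- make_view_noise_records(30, seed = 20)
  rel <- run_reliability(rec, fusion_config(epochs = 60),
                         n_repetitions = 5, base_seed = 7)
  expect_equal(rel$n_repetitions, 5)
  expect_equal(nrow(rel$per_repetition), 10)
  expect_setequal(unique(rel$per_repetition$model), c("fused", "cv_only"))

  # summary statistics are recomputable from the stored list
  fused_mae <- rel$per_repetition$mae[rel$per_repetition$model == "fused"]
  expect_equal(rel$summary$mean[rel$summary$model == "fused" &
                                  rel$summary$metric == "mae"],
               mean(fused_mae))

  # same base seed reproduces the whole summary; n = 1 equals one run
  rel2 <- run_reliability(rec, fusion_config(epochs = 60),
                          n_repetitions = 5, base_seed = 7)
  expect_identical(rel$per_repetition, rel2$per_repetition)

  one <- run_reliability(rec, fusion_config(epochs = 60),
                         n_repetitions = 1, base_seed = 3)
  fit <- train_fusion(rec, {
    cfg <- fusion_config(epochs = 60); cfg$seed <- 4L; cfg
  })
  test <- fit$records[fit$split$test, ]
  expect_equal(one$per_repetition$mae[1],
               mean(abs(predict(fit) - test$nsa_ap_clinician)))
})
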