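test_that("an ideal line is detected at its angle; a blank region yields no lines", {
  img <- render_line_image(30)
  ls <- detect_lines(img, roi(1, 1, 100, 100, "femur"),
                     hough_params(min_line_length = 40))
  expect_gt(nrow(ls$lines), 0)
  expect_true(all(abs(ls$lines$angle - 30) <= 1))

  blank <- matrix(50, 80, 80)
  empty <- detect_lines(blank, roi(1, 1, 80, 80, "femur"), hough_params())
  expect_equal(nrow(empty$lines), 0)
  expect_error(median_angle(empty), "no lines detected")
})

test_that("a vertical line reports +90, never -90 (half-open convention)", {
  img <- render_line_image(90)
  ls <- detect_lines(img, roi(1, 1, 100, 100, "femur"),
                     hough_params(min_line_length = 40))
  expect_gt(nrow(ls$lines), 0)
  expect_true(all(ls$lines$angle == 90))
})

test_that("rotating the line rotates the detected median angle accordingly", {
  base <- 40
  m0 <- median_angle(detect_lines(render_line_image(base),
                                  roi(1, 1, 100, 100, "femur"),
                                  hough_params(min_line_length = 40)))
  for (delta in c(-25, 10, 35)) {
    m1 <- median_angle(detect_lines(render_line_image(base + delta),
                                    roi(1, 1, 100, 100, "femur"),
                                    hough_params(min_line_length = 40)))
    expect_lt(abs((m1 - m0) - delta), 1)
  }
})

test_that("median_angle follows the even/odd rules and ignores outliers", {
  expect_equal(median_angle(line_set_from_angles(c(30, 30, 90))), 30)
  expect_equal(median_angle(line_set_from_angles(c(10, 20, 30, 40))), 25)
  expect_equal(median_angle(line_set_from_angles(c(-55, -54, -56, 80))),
               -54.5)
})

test_that("the NSA is the sum of absolute median angles, order-invariant", {
  f <- line_set_from_angles(c(80, 80, 81))
  p <- line_set_from_angles(c(-55, -56, -54))
  est <- compute_nsa(f, p, "AP")
  expect_equal(est$nsa, abs(80) + abs(-55))
  expect_equal(est$view, "AP")

  est_b <- compute_nsa(line_set_from_angles(c(90, 90)),
                       line_set_from_angles(c(0, 0)), "lateral")
  expect_equal(est_b$nsa, 90)

  # permutation invariance of the aggregation
  perm <- line_set_from_angles(c(-54, -55, -56))
  expect_equal(compute_nsa(f, perm, "AP")$nsa, est$nsa)
})

test_that("full single-view chain recovers the scene NSA on clean images", {
  for (seed in c(21, 22, 23)) {
    co <- generate_cohort(1, seed = seed, noise_sigma = 5)
    s <- co$scenes[[1]]
    est <- estimate_view_nsa(s$ap_image, shared_bank)$estimate
    expect_lt(abs(est$nsa - s$true_nsa_ap), 3)
  }
})

test_that("tuning-set split reproduces the 30% / 70% partition", {
  sp <- split_tuning(57, fraction = 0.3, seed = 1)
  expect_length(sp$tuning, 17)
  expect_length(sp$evaluation, 40)
  expect_identical(sp, split_tuning(57, fraction = 0.3, seed = 1))
  expect_setequal(c(sp$tuning, sp$evaluation), 1:57)
})

test_that("Hough tuning returns the grid point with minimal tuning error", {
  co <- generate_cohort(3, seed = 31, noise_sigma = 8)
  cfg <- nsa_config()

  # single scene, single grid point: that point comes back
  single <- tune_hough(co$scenes[1], min_line_lengths = 18,
                       vote_thresholds = 22, templates = shared_bank,
                       config = cfg)
  expect_equal(single$params$min_line_length, 18)
  expect_equal(single$params$vote_threshold, 22)

  # 3x3 grid vs an exhaustive oracle over the same grid
  mls <- c(14, 20, 26); vts <- c(15, 20, 25)
  tuned <- tune_hough(co$scenes, min_line_lengths = mls,
                      vote_thresholds = vts, templates = shared_bank,
                      config = cfg)
  oracle_err <- function(ml, vt) {
    c2 <- cfg
    c2$hough$min_line_length <- ml
    c2$hough$vote_threshold <- vt
    mean(vapply(co$scenes, function(sc) {
      est <- tryCatch(
        estimate_view_nsa(sc$ap_image, shared_bank, c2, "AP")$estimate$nsa,
        error = function(e) NA_real_)
      if (is.na(est)) 180 else abs(est - sc$true_nsa_ap)
    }, numeric(1)))
  }
  grid_errs <- outer(mls, vts, Vectorize(oracle_err))
  expect_lte(tuned$error, min(grid_errs) + 1e-12)
})
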