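test_that("the trapezoid axis joins segment midpoints with the stated orientation", {
  p <- landmark_pair(rbind(c(0, 0), c(2, 0)), rbind(c(0, 4), c(2, 4)),
                     "femoral_neck")
  ax <- trapezoid_axis(p)
  expect_equal(unname(ax$point), c(1, 0))
  expect_equal(ax$direction, c(0, 1))

  p2 <- landmark_pair(rbind(c(0, 0), c(0, 2)), rbind(c(4, 0), c(4, 2)),
                      "femoral_shaft")
  expect_equal(trapezoid_axis(p2)$direction, c(1, 0))

  expect_error(landmark_pair(rbind(c(1, 1), c(1, 1)),
                             rbind(c(0, 0), c(1, 0))), "degenerate")
  # distinct segments sharing a midpoint leave the axis undefined
  shared <- landmark_pair(rbind(c(0, 0), c(2, 2)), rbind(c(0, 2), c(2, 0)))
  expect_error(trapezoid_axis(shared), "coincide")
})

test_that("axes_angle measures the directed angle in [0, 180]", {
  expect_equal(axes_angle(c(0, 1), c(1, 0)), 90)
  expect_equal(axes_angle(c(0, 1), c(1, -1) / sqrt(2)), 135)
  expect_equal(axes_angle(c(1, 0), c(1, 0)), 0)
  expect_error(axes_angle(c(0, 0), c(1, 0)), "zero direction")
})

test_that("scene landmarks reproduce the generating geometry exactly", {
  for (pars in list(c(80, -55), c(90, -45), c(78, -72), c(85, -65))) {
    sc <- generate_scene(scene_params(shaft_angle = pars[1],
                                      stem_angle = pars[2],
                                      noise_sigma = 0))
    expect_equal(scene_trapezoid_nsa(sc), sc$true_nsa_ap,
                 tolerance = 1e-9)
    # the neck-quadrangle axis is parallel to the rendered stem axis
    q <- sc$neck_quadrangle
    ax <- trapezoid_axis(landmark_pair(q[1:2, ], q[3:4, ], "stem"))
    stem_dir <- sc$geometry$d_st
    cross <- ax$direction[1] * stem_dir[2] - ax$direction[2] * stem_dir[1]
    expect_lt(abs(cross), 1e-9)
  }
})

test_that("the trapezoid NSA is invariant to rotation and scaling of the landmarks", {
  sc <- generate_scene(scene_params(shaft_angle = 82, stem_angle = -53,
                                    noise_sigma = 0))
  q <- sc$neck_quadrangle
  s1 <- sc$shaft_segment_pair[[1]]
  s2 <- sc$shaft_segment_pair[[2]]
  nsa0 <- trapezoid_nsa(landmark_pair(q[1:2, ], q[3:4, ], "stem"),
                        landmark_pair(s1, s2, "femoral_shaft"))

  transform <- function(pts, theta, k) {
    R <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
    t(R %*% t(pts * k))
  }
  # rotations modest enough to keep the distal-proximal reading intact
  for (theta in c(-0.5, -0.2, 0.15, 0.4)) {
    for (k in c(0.35, 1, 12.5)) {
      nsa1 <- trapezoid_nsa(
        landmark_pair(transform(q[1:2, ], theta, k),
                      transform(q[3:4, ], theta, k), "stem"),
        landmark_pair(transform(s1, theta, k),
                      transform(s2, theta, k), "femoral_shaft"))
      expect_equal(nsa1, nsa0, tolerance = 1e-9)
    }
  }
})

test_that("landmark CSV round trip reproduces per-hip clinician NSAs", {
  scs <- list(generate_scene(scene_params(shaft_angle = 84,
                                          stem_angle = -51,
                                          noise_sigma = 0)),
              generate_scene(scene_params(shaft_angle = 79,
                                          stem_angle = -66,
                                          noise_sigma = 0)))
  rows <- do.call(rbind, lapply(seq_along(scs), function(i) {
    sc <- scs[[i]]
    q <- sc$neck_quadrangle
    seg_row <- function(structure, seg)
      data.frame(hip_id = sprintf("hip%d", i), structure = structure,
                 x1 = seg[1, 1], y1 = seg[1, 2],
                 x2 = seg[2, 1], y2 = seg[2, 2])
    rbind(seg_row("stem", q[1:2, ]), seg_row("stem", q[3:4, ]),
          seg_row("femoral_shaft", sc$shaft_segment_pair[[1]]),
          seg_row("femoral_shaft", sc$shaft_segment_pair[[2]]))
  }))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE)
  got <- landmarks_nsa(read_landmarks(path))
  expect_equal(got$nsa_clinician[match(c("hip1", "hip2"), got$hip_id)],
               vapply(scs, `[[`, numeric(1), "true_nsa_ap"),
               tolerance = 1e-9)
  expect_error(read_landmarks(withr::local_tempfile(lines = "a,b",
                                                    fileext = ".csv")),
               "must have columns")
})
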