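# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; nothing is read from disk.

# one template bank reused across tests (deterministic)
shared_bank <- generate_template_bank(5, seed = 1)

# records-level synthetic cohort: each radiographic view is an independent
# noisy reading of the clinician (anatomical) NSA
make_view_noise_records <- function(n = 57, seed = 1, sigma_ap = 3.5,
                                    sigma_lat = 3.5,
                                    nsa_range = c(120, 160)) {
  set.seed(seed)
  truth <- runif(n, nsa_range[1], nsa_range[2])
  data.frame(hip_id = sprintf("h%03d", seq_len(n)),
             nsa_ap_cv = truth + rnorm(n, 0, sigma_ap),
             nsa_lateral_cv = truth + rnorm(n, 0, sigma_lat),
             nsa_ap_clinician = truth,
             stringsAsFactors = FALSE)
}

# a synthetic line-only image: band of given width through the image
# center at a signed from-horizontal angle
render_line_image <- function(angle_deg, size = 100, len = 80, width = 3,
                              bg = 0, fg = 200) {
  img <- matrix(bg, size, size)
  a <- angle_deg * pi / 180
  u <- c(cos(a), -sin(a))            # x, y (row) direction on screen
  c0 <- c(size / 2, size / 2)
  p1 <- c0 - len / 2 * u
  p2 <- c0 + len / 2 * u
  X <- matrix(seq_len(size), size, size, byrow = TRUE)
  Y <- matrix(seq_len(size), size, size)
  v <- p2 - p1
  l <- sqrt(sum(v^2))
  uu <- v / l
  t <- (X - p1[1]) * uu[1] + (Y - p1[2]) * uu[2]
  d <- (X - p1[1]) * (-uu[2]) + (Y - p1[2]) * uu[1]
  img[t >= 0 & t <= l & abs(d) <= width / 2] <- fg
  img
}

line_set_from_angles <- function(angles) {
  structure(list(lines = data.frame(radius = 0, angle = angles,
                                    length = 50, votes = 50,
                                    x1 = 0, y1 = 0, x2 = 1, y2 = 1),
                 source_roi = roi(1, 1, 10, 10, "femur"),
                 params = hough_params()),
            class = "line_set")
}

# --- independent oracles -------------------------------------------------

# elementwise-loop mean squared error
oracle_mse <- function(a, b) {
  s <- 0
  for (j in seq_len(ncol(a)))
    for (i in seq_len(nrow(a)))
      s <- s + (a[i, j] - b[i, j])^2
  s / length(a)
}

# brute-force template search: templates in order, scales ascending,
# positions row-major, strict improvement (first encounter wins ties)
oracle_match <- function(image, templates, scales) {
  resize <- function(img, s) {
    h2 <- max(1L, as.integer(round(nrow(img) * s)))
    w2 <- max(1L, as.integer(round(ncol(img) * s)))
    ri <- pmin(nrow(img), floor((seq_len(h2) - 0.5) * nrow(img) / h2) + 1)
    ci <- pmin(ncol(img), floor((seq_len(w2) - 0.5) * ncol(img) / w2) + 1)
    img[ri, ci, drop = FALSE]
  }
  best <- list(mse = Inf)
  for (ti in seq_along(templates)) {
    for (s in sort(scales)) {
      tpl <- resize(templates[[ti]], s)
      h <- nrow(tpl); w <- ncol(tpl)
      if (h > nrow(image) || w > ncol(image)) next
      for (y0 in 0:(nrow(image) - h)) {
        for (x0 in 0:(ncol(image) - w)) {
          win <- image[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), drop = FALSE]
          m <- sum((win - tpl)^2) / (h * w)
          if (m < best$mse)
            best <- list(mse = m, x = x0 + 1L, y = y0 + 1L,
                         template_index = ti, scale = s,
                         width = w, height = h)
        }
      }
    }
  }
  best
}

# textbook Spearman: 1 - 6 sum d^2 / (n(n^2-1)) for distinct values, with
# the large-sample t p-value
oracle_spearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  rs <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
  tstat <- rs * sqrt((n - 2) / (1 - rs^2))
  list(rs = rs, p_value = 2 * stats::pt(-abs(tstat), n - 2))
}

# textbook Kruskal-Wallis H with tie correction
oracle_kruskal <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)
  sizes <- vapply(groups, length, integer(1))
  idx <- split(seq_len(n), rep(seq_along(groups), sizes))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(idx, function(i) sum(r[i])^2 / length(i), numeric(1))) -
    3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / corr
  list(H = h, p_value = stats::pchisq(h, length(groups) - 1,
                                      lower.tail = FALSE))
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_script <- function() system.file("cli", "nsa-vision.R",
                                     package = "nsavision")
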