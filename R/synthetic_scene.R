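#' Parameters of a synthetic hip-resurfacing radiograph
#'
#' Bundles and validates the geometry of a rendered scene: a bright
#' femoral-shaft band at a known signed angle and a resurfacing prosthesis
#' (hemispherical cup plus short stem) whose stem axis has a known signed
#' angle. All angles are signed degrees from the image horizontal in
#' `(-90, 90]`; the radiographic neck-shaft angle implied by the scene is
#' `abs(shaft_angle) + abs(stem_angle)` and must lie in the anatomically
#' plausible `[90, 180]` range, which forces the two angles to carry
#' opposite signs (the shaft leans one way, the stem the other, as on an
#' AP film). The shaft must be within 45 degrees of vertical for the
#' rendered layout.
#'
#' @param image_width,image_height image size in pixels.
#' @param shaft_angle signed femoral-shaft axis angle, degrees from
#'   horizontal in `(-90, 90]`.
#' @param stem_angle signed prosthesis-stem axis angle, degrees from
#'   horizontal in `(-90, 90]`.
#' @param shaft_width width of the rendered shaft band, pixels.
#' @param cup_radius radius of the hemispherical cup, pixels.
#' @param stem_length length of the stem axis from its base to the cup
#'   center, pixels.
#' @param noise_sigma standard deviation of additive Gaussian background
#'   noise on the 0-255 intensity scale.
#' @param lateral_perturbation_sigma standard deviation, degrees, of the
#'   normal perturbation applied to the stem angle in the lateral view.
#' @param seed integer seed; identical seed and parameters give
#'   bit-identical images.
#' @return An object of class `scene_params` (a validated list).
#' @seealso [generate_scene()]
#' @export
scene_params <- function(image_width = 192, image_height = 192,
                         shaft_angle = 82, stem_angle = -52,
                         shaft_width = 14, cup_radius = 16,
                         stem_length = 48, noise_sigma = 8,
                         lateral_perturbation_sigma = 3, seed = 1L) {
  p <- list(image_width = as.integer(image_width),
            image_height = as.integer(image_height),
            shaft_angle = shaft_angle, stem_angle = stem_angle,
            shaft_width = shaft_width, cup_radius = cup_radius,
            stem_length = stem_length, noise_sigma = noise_sigma,
            lateral_perturbation_sigma = lateral_perturbation_sigma,
            seed = as.integer(seed))
  if (p$image_width < 64 || p$image_height < 64)
    stop("image must be at least 64x64 pixels", call. = FALSE)
  for (a in c("shaft_angle", "stem_angle"))
    if (p[[a]] <= -90 || p[[a]] > 90)
      stop(sprintf("`%s` must lie in (-90, 90]", a), call. = FALSE)
  nsa <- abs(p$shaft_angle) + abs(p$stem_angle)
  if (nsa < 90 || nsa > 180)
    stop("abs(shaft_angle) + abs(stem_angle) must lie in [90, 180]",
         call. = FALSE)
  if (p$shaft_angle * p$stem_angle > 0)
    stop("shaft_angle and stem_angle must have opposite signs ",
         "(the shaft and stem lean to opposite sides of vertical)",
         call. = FALSE)
  if (abs(p$shaft_angle) < 45)
    stop("abs(shaft_angle) must be >= 45 (near-vertical shaft layout)",
         call. = FALSE)
  if (p$shaft_width < 4 || p$cup_radius < 4 || p$stem_length < 8)
    stop("shaft_width and cup_radius must be >= 4, stem_length >= 8",
         call. = FALSE)
  if (p$noise_sigma < 0 || p$lateral_perturbation_sigma < 0)
    stop("noise and perturbation sigmas must be non-negative", call. = FALSE)
  structure(p, class = "scene_params")
}

# rendering intensities (8-bit scale)
.BG_INTENSITY <- 30
.SHAFT_INTENSITY <- 180
.PROSTHESIS_INTENSITY <- 250
.SCENE_MARGIN <- 5

# membership mask of the band of half-width hw around the segment p1 -> p2,
# evaluated on the full pixel grid (matrix [row, col])
.band_mask <- function(W, H, p1, p2, hw) {
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  Y <- matrix(seq_len(H), H, W)
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  u <- v / len
  dx <- X - p1[1]
  dy <- Y - p1[2]
  t <- dx * u[1] + dy * u[2]
  d <- dx * (-u[2]) + dy * u[1]
  t >= 0 & t <= len & abs(d) <= hw
}

.disc_mask <- function(W, H, center, r) {
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  Y <- matrix(seq_len(H), H, W)
  (X - center[1])^2 + (Y - center[2])^2 <= r^2
}

# derived layout of one view; errors when any element leaves the margins
.scene_geometry <- function(p, stem_angle) {
  W <- p$image_width; H <- p$image_height
  m <- .SCENE_MARGIN
  sgn <- if (p$shaft_angle >= 0) 1 else -1
  p0 <- c(W * (0.5 + 0.09 * sgn), H * 0.55)

  u_sh <- unit_from_angle(p$shaft_angle)
  d_sh <- if (u_sh[2] < 0) -u_sh else u_sh        # distal = downward
  hw_sh <- p$shaft_width / 2
  # longest shaft that keeps the whole band inside the margin box
  lim <- function(pos, dir, lo, hi) {
    if (abs(dir) < 1e-12) return(Inf)
    t1 <- (lo - pos) / dir; t2 <- (hi - pos) / dir
    max(t1, t2)
  }
  t_max <- min(lim(p0[1], d_sh[1], m + hw_sh, W - m - hw_sh),
               lim(p0[2], d_sh[2], m + hw_sh, H - m - hw_sh))
  shaft_len <- floor(t_max)
  if (!is.finite(shaft_len) || shaft_len < 2 * p$shaft_width)
    stop("scene geometry out of bounds: shaft does not fit in the image",
         call. = FALSE)
  p_bot <- p0 + shaft_len * d_sh

  u_st <- unit_from_angle(stem_angle)
  d_st <- if (u_st[2] > 0) -u_st else u_st        # proximal = upward
  if (abs(d_st[2]) < 1e-12) d_st <- c(-abs(d_st[1]) * sgn, 0)
  cup <- p0 + p$stem_length * d_st
  hw_st <- max(3, round(p$cup_radius * 0.28))
  n_st <- c(-d_st[2], d_st[1])

  corners <- rbind(p0 + hw_st * n_st, p0 - hw_st * n_st,
                   cup + hw_st * n_st, cup - hw_st * n_st,
                   cup + c(p$cup_radius, 0), cup - c(p$cup_radius, 0),
                   cup + c(0, p$cup_radius), cup - c(0, p$cup_radius))
  if (any(corners[, 1] < m) || any(corners[, 1] > W - m) ||
      any(corners[, 2] < m) || any(corners[, 2] > H - m))
    stop("scene geometry out of bounds: prosthesis does not fit in the image",
         call. = FALSE)

  list(p0 = p0, p_bot = p_bot, d_sh = d_sh, d_st = d_st, n_st = n_st,
       cup_center = cup, shaft_len = shaft_len, hw_sh = hw_sh,
       hw_st = hw_st)
}

# noiseless rendering of one view; returns the image and its masks
.render_view <- function(p, stem_angle) {
  g <- .scene_geometry(p, stem_angle)
  W <- p$image_width; H <- p$image_height
  shaft <- .band_mask(W, H, g$p0, g$p_bot, g$hw_sh)
  stem <- .band_mask(W, H, g$p0, g$cup_center, g$hw_st)
  cup <- .disc_mask(W, H, g$cup_center, p$cup_radius)
  img <- matrix(.BG_INTENSITY, H, W)
  img[shaft] <- .SHAFT_INTENSITY
  pros <- stem | cup
  img[pros] <- .PROSTHESIS_INTENSITY
  rows <- range(which(rowSums(pros) > 0))
  cols <- range(which(colSums(pros) > 0))
  list(image = img, geometry = g, shaft_mask = shaft,
       prosthesis_mask = pros,
       prosthesis_center = c(mean(cols), mean(rows)),
       prosthesis_bbox = c(x = cols[1], y = rows[1],
                           width = diff(cols) + 1, height = diff(rows) + 1))
}

.add_noise <- function(img, sigma) {
  if (sigma <= 0) return(img)
  noisy <- img + matrix(stats::rnorm(length(img), 0, sigma),
                        nrow(img), ncol(img))
  round(pmin(pmax(noisy, 0), 255))
}

# keep a perturbed stem angle renderable and anatomically valid
.clamp_stem <- function(stem_angle, shaft_angle) {
  s <- if (stem_angle != 0) sign(stem_angle) else -sign(shaft_angle)
  mag <- abs(stem_angle)
  lo <- max(2, 90.2 - abs(shaft_angle))
  hi <- min(88, 179.5 - abs(shaft_angle))
  s * min(hi, max(lo, mag))
}

#' Generate a synthetic AP/lateral radiograph pair with known geometry
#'
#' Renders an anterior-posterior (AP) view from `params` and a lateral view
#' whose stem angle is the AP stem angle plus a normal draw with standard
#' deviation `params$lateral_perturbation_sigma` (or plus the fixed
#' `lateral_offset` when supplied, as the cohort generator does), so the two
#' views disagree in a controlled way. The ground-truth AP neck-shaft angle
#' is `abs(shaft_angle) + abs(stem_angle)` of the unperturbed AP geometry,
#' and the emitted landmarks (neck quadrangle on the stem, transverse
#' segment pair on the shaft) are constructed so that the trapezoid
#' technique recovers it exactly.
#'
#' @param params a [scene_params()] object.
#' @param lateral_offset optional fixed perturbation, degrees, added to the
#'   stem angle in the lateral view instead of a random draw.
#' @return An object of class `synthetic_scene`: a list with `ap_image` and
#'   `lateral_image` (numeric matrices, 0-255), `true_nsa_ap`,
#'   `true_nsa_lateral`, `neck_quadrangle` (4 x 2 matrix of (x, y) points),
#'   `shaft_segment_pair` (list of two 2 x 2 matrices), `prosthesis_center`,
#'   plus rendering masks and geometry used by the test oracles.
#' @examples
#' sc <- generate_scene(scene_params(shaft_angle = 80, stem_angle = -55))
#' sc$true_nsa_ap  # 135
#' @export
generate_scene <- function(params, lateral_offset = NULL) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  with_seed(p$seed, {
    ap <- .render_view(p, p$stem_angle)
    ap_img <- .add_noise(ap$image, p$noise_sigma)
    delta <- if (is.null(lateral_offset))
      stats::rnorm(1, 0, p$lateral_perturbation_sigma)
    else lateral_offset
    stem_lat <- .clamp_stem(p$stem_angle + delta, p$shaft_angle)
    lat <- .render_view(p, stem_lat)
    lat_img <- .add_noise(lat$image, p$noise_sigma)

    g <- ap$geometry
    # landmarks: transverse segments across the stem (neck quadrangle)
    # and across the shaft; midpoints lie exactly on the respective axes
    a1 <- g$p0 + 0.35 * p$stem_length * g$d_st
    a2 <- g$p0 + 0.80 * p$stem_length * g$d_st
    quad <- rbind(a1 + g$hw_st * g$n_st, a1 - g$hw_st * g$n_st,
                  a2 + g$hw_st * g$n_st, a2 - g$hw_st * g$n_st)
    colnames(quad) <- c("x", "y")
    n_sh <- c(-g$d_sh[2], g$d_sh[1])
    s1 <- g$p0 + 0.30 * g$shaft_len * g$d_sh
    s2 <- g$p0 + 0.75 * g$shaft_len * g$d_sh
    seg <- function(center) {
      m <- rbind(center + g$hw_sh * n_sh, center - g$hw_sh * n_sh)
      colnames(m) <- c("x", "y")
      m
    }

    structure(list(
      ap_image = ap_img, lateral_image = lat_img,
      true_nsa_ap = abs(p$shaft_angle) + abs(p$stem_angle),
      true_nsa_lateral = abs(p$shaft_angle) + abs(stem_lat),
      neck_quadrangle = quad,
      shaft_segment_pair = list(seg(s1), seg(s2)),
      prosthesis_center = ap$prosthesis_center,
      prosthesis_bbox = ap$prosthesis_bbox,
      shaft_mask = ap$shaft_mask,
      prosthesis_mask = ap$prosthesis_mask,
      stem_angle_lateral = stem_lat,
      geometry = g, params = p), class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %dx%d px, true NSA AP %.2f deg, lateral %.2f deg\n",
              x$params$image_width, x$params$image_height,
              x$true_nsa_ap, x$true_nsa_lateral))
  invisible(x)
}

#' Generate a bank of reference prosthesis templates
#'
#' Renders `n_templates` clean prosthesis images (cup plus stem, no shaft,
#' no noise) at cup radii spread across `cup_radius_range` and varied stem
#' orientations, cropped to the prosthesis bounding box plus a small
#' background margin. These play the role of the reference prosthesis
#' images used by the mean-squared-error matcher; the matcher's scale
#' sweep fills in implant sizes between the bank's radii.
#'
#' @param n_templates number of templates (default 5).
#' @param cup_radius_range length-2 numeric range of cup radii, pixels.
#' @param seed integer seed; a fixed seed gives an identical bank.
#' @return A list of `n_templates` grayscale matrices (0-255).
#' @export
generate_template_bank <- function(n_templates = 5,
                                   cup_radius_range = c(12, 20),
                                   seed = 1L) {
  if (n_templates < 1) stop("n_templates must be >= 1", call. = FALSE)
  radii <- if (n_templates == 1) mean(cup_radius_range) else
    seq(cup_radius_range[1], cup_radius_range[2], length.out = n_templates)
  base_angles <- if (n_templates == 1) -52 else
    seq(-68, -38, length.out = n_templates)
  with_seed(seed, {
    jitter <- stats::rnorm(n_templates, 0, 2)
    lapply(seq_len(n_templates), function(i) {
      r <- radii[i]
      stem_angle <- max(-85, min(-20, base_angles[i] + jitter[i]))
      p <- scene_params(image_width = max(96, ceiling(8 * r)),
                        image_height = max(96, ceiling(8 * r)),
                        shaft_angle = 85, stem_angle = stem_angle,
                        cup_radius = r, stem_length = round(3 * r),
                        noise_sigma = 0, seed = 1L)
      v <- .render_view(p, p$stem_angle)
      img <- matrix(.BG_INTENSITY, p$image_height, p$image_width)
      img[v$prosthesis_mask] <- .PROSTHESIS_INTENSITY
      bb <- v$prosthesis_bbox
      mar <- 4
      rows <- max(1, bb["y"] - mar):min(nrow(img), bb["y"] + bb["height"] - 1 + mar)
      cols <- max(1, bb["x"] - mar):min(ncol(img), bb["x"] + bb["width"] - 1 + mar)
      img[rows, cols, drop = FALSE]
    })
  })
}

#' Draw per-hip scene parameters for a synthetic cohort
#'
#' Samples the study conditions for `n_hips` hips: an anatomical
#' (clinician) neck-shaft angle uniform over `nsa_range`, a near-vertical
#' shaft angle uniform over `shaft_range`, and independent per-view
#' positioning perturbations `eta_AP, eta_LAT ~ Normal(0, view_sigma)` of
#' the projected stem angle. The AP scene is rendered at
#' `nsa_clinician + eta_AP` and the lateral view at
#' `nsa_clinician + eta_LAT`, so each radiographic view is an independent
#' noisy projection of the anatomical angle -- the regime in which fusing
#' the two views recovers accuracy lost to positioning variability. Hips
#' are grouped into patients with a mostly-bilateral structure
#' (approximately 26 bilateral pairs per 57 hips).
#'
#' @param n_hips number of hips.
#' @param seed integer seed.
#' @param nsa_range range of anatomical neck-shaft angles, degrees.
#' @param shaft_range range of shaft angles, degrees from horizontal.
#' @param view_sigma standard deviation, degrees, of the per-view
#'   positioning perturbation.
#' @param cup_radius_range range of cup radii, pixels.
#' @return A data frame with one row per hip: `hip_id`, `patient_id`,
#'   `nsa_clinician`, `shaft_angle`, `stem_angle`, `lateral_offset`,
#'   `cup_radius`, `seed`.
#' @export
draw_cohort_params <- function(n_hips, seed = 1L, nsa_range = c(120, 160),
                               shaft_range = c(78, 88), view_sigma = 3.5,
                               cup_radius_range = c(13, 19)) {
  if (n_hips < 1) stop("n_hips must be >= 1", call. = FALSE)
  with_seed(seed, {
    nsa <- stats::runif(n_hips, nsa_range[1], nsa_range[2])
    sa <- stats::runif(n_hips, shaft_range[1], shaft_range[2])
    eta_ap <- stats::rnorm(n_hips, 0, view_sigma)
    eta_lat <- stats::rnorm(n_hips, 0, view_sigma)
    r <- stats::runif(n_hips, cup_radius_range[1], cup_radius_range[2])
    stem <- vapply(seq_len(n_hips), function(i)
      .clamp_stem(-(nsa[i] + eta_ap[i] - sa[i]), sa[i]), numeric(1))
    n_pairs <- min(floor(n_hips / 2), round(n_hips * 26 / 57))
    patient <- integer(n_hips)
    if (n_pairs > 0)
      patient[seq_len(2 * n_pairs)] <- rep(seq_len(n_pairs), each = 2)
    extra <- which(patient == 0L)
    patient[extra] <- n_pairs + seq_along(extra)
    data.frame(
      hip_id = sprintf("hip%03d", seq_len(n_hips)),
      patient_id = sprintf("pat%03d", patient),
      nsa_clinician = nsa,
      shaft_angle = sa,
      stem_angle = stem,
      lateral_offset = eta_ap - eta_lat,
      cup_radius = round(r, 1),
      seed = vapply(seq_len(n_hips), function(i) child_seed(seed, i),
                    integer(1)),
      stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic cohort of AP/lateral radiograph pairs
#'
#' Draws per-hip parameters with [draw_cohort_params()], renders every
#' scene, and (optionally) writes the cohort to disk in the layout the
#' pipeline consumes: `<hipID>_AP.png` and `<hipID>_LAT.png` 8-bit
#' grayscale files plus a `truth.csv` table with columns `hip_id`,
#' `true_nsa_ap`, `true_nsa_lateral`, `nsa_ap_clinician`, `patient_id`,
#' `center_x_ap`, `center_y_ap`.
#'
#' @param n_hips number of hips.
#' @param dir output directory, created if needed; `NULL` keeps the cohort
#'   in memory only.
#' @param seed integer seed.
#' @param noise_sigma additive image noise standard deviation (0-255 scale).
#' @param image_width,image_height image size in pixels.
#' @param ... further arguments passed to [draw_cohort_params()].
#' @return Invisibly, a list with `scenes` (list of [generate_scene()]
#'   results), `truth` (data frame), and `dir`.
#' @export
generate_cohort <- function(n_hips, dir = NULL, seed = 1L, noise_sigma = 8,
                            image_width = 192, image_height = 192, ...) {
  par <- draw_cohort_params(n_hips, seed = seed, ...)
  scenes <- lapply(seq_len(n_hips), function(i) {
    p <- scene_params(image_width = image_width,
                      image_height = image_height,
                      shaft_angle = par$shaft_angle[i],
                      stem_angle = par$stem_angle[i],
                      cup_radius = par$cup_radius[i],
                      noise_sigma = noise_sigma,
                      seed = par$seed[i])
    generate_scene(p, lateral_offset = par$lateral_offset[i])
  })
  truth <- data.frame(
    hip_id = par$hip_id,
    true_nsa_ap = vapply(scenes, `[[`, numeric(1), "true_nsa_ap"),
    true_nsa_lateral = vapply(scenes, `[[`, numeric(1), "true_nsa_lateral"),
    nsa_ap_clinician = par$nsa_clinician,
    patient_id = par$patient_id,
    center_x_ap = vapply(scenes, function(s) s$prosthesis_center[1],
                         numeric(1)),
    center_y_ap = vapply(scenes, function(s) s$prosthesis_center[2],
                         numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir))
      stop(sprintf("cannot create output directory '%s'", dir),
           call. = FALSE)
    for (i in seq_len(n_hips)) {
      write_radiograph(scenes[[i]]$ap_image,
                       file.path(dir, paste0(par$hip_id[i], "_AP.png")))
      write_radiograph(scenes[[i]]$lateral_image,
                       file.path(dir, paste0(par$hip_id[i], "_LAT.png")))
    }
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(list(scenes = scenes, truth = truth, dir = dir))
}

#' Read and write 8-bit grayscale radiograph images
#'
#' Thin wrappers over the PNG codec keeping the package's 0-255 numeric
#' matrix convention (rows are image rows, columns are image columns).
#' Color input is collapsed with [to_grayscale()] on read.
#'
#' @param path file path of a PNG image.
#' @param image numeric matrix with intensities in 0-255.
#' @return `read_radiograph()` returns a numeric matrix in 0-255;
#'   `write_radiograph()` returns `path` invisibly.
#' @export
read_radiograph <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , seq_len(min(3, dim(arr)[3]))]
  round(to_grayscale(arr * 255))
}

#' @rdname read_radiograph
#' @export
write_radiograph <- function(image, path) {
  stop_if_not_image(image)
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}
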