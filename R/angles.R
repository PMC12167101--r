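#' Hough line-detection parameters
#'
#' @param min_line_length minimum segment length in pixels.
#' @param vote_threshold minimum accumulator votes for a candidate line.
#' @param canny_low,canny_high hysteresis thresholds of the Canny edge
#'   extraction that precedes the accumulator (Sobel magnitude units on an
#'   8-bit image).
#' @param angle_resolution accumulator angle step, degrees.
#' @param rho_resolution accumulator radius step, pixels.
#' @param max_gap largest along-line gap, pixels, bridged when linking edge
#'   pixels into a segment.
#' @return An object of class `hough_params`.
#' @export
hough_params <- function(min_line_length = 18, vote_threshold = 15,
                         canny_low = 50, canny_high = 150,
                         angle_resolution = 1, rho_resolution = 1,
                         max_gap = 3) {
  if (min_line_length < 1 || vote_threshold < 1)
    stop("min_line_length and vote_threshold must be >= 1", call. = FALSE)
  if (canny_low >= canny_high)
    stop("canny_low must be < canny_high", call. = FALSE)
  if (angle_resolution <= 0 || rho_resolution <= 0 || max_gap < 0)
    stop("invalid resolution or gap parameter", call. = FALSE)
  structure(list(min_line_length = min_line_length,
                 vote_threshold = vote_threshold,
                 canny_low = canny_low, canny_high = canny_high,
                 angle_resolution = angle_resolution,
                 rho_resolution = rho_resolution,
                 max_gap = max_gap), class = "hough_params")
}

#' Detect straight line segments inside a region of interest
#'
#' Crops the ROI, extracts a Canny edge map, and runs a Hough accumulator
#' over (radius, angle); every accumulator cell reaching `vote_threshold`
#' is expanded back into contiguous runs of its voting edge pixels, and
#' runs at least `min_line_length` long become detected segments. Segment
#' angles are reported in the signed from-horizontal convention
#' `(-90, 90]` (a vertical line is +90, never -90).
#'
#' @param image grayscale numeric matrix (0-255).
#' @param roi a [roi()] inside the image.
#' @param params a [hough_params()] object.
#' @return An object of class `line_set`: a list with `lines` (data frame
#'   with columns `radius`, `angle`, `length`, `votes`, `x1`, `y1`, `x2`,
#'   `y2`, in ROI-local pixel coordinates), `source_roi`, and `params`.
#'   The data frame may have zero rows (e.g. a blank ROI).
#' @export
detect_lines <- function(image, roi, params = hough_params()) {
  stop_if_not_image(image)
  stopifnot(inherits(roi, "roi"), inherits(params, "hough_params"))
  crop <- .crop(image, roi)
  if (length(crop) == 0L) stop("empty ROI crop", call. = FALSE)
  edges <- canny_cpp(crop, params$canny_low, params$canny_high)
  seg <- hough_segments_cpp(edges, params$rho_resolution,
                            params$angle_resolution,
                            as.integer(params$vote_threshold),
                            params$min_line_length, params$max_gap)
  lines <- data.frame(radius = seg[, "rho"], angle = seg[, "angle"],
                      length = seg[, "length"], votes = seg[, "votes"],
                      x1 = seg[, "x1"] + 1, y1 = seg[, "y1"] + 1,
                      x2 = seg[, "x2"] + 1, y2 = seg[, "y2"] + 1)
  structure(list(lines = lines, source_roi = roi, params = params),
            class = "line_set")
}

#' @export
print.line_set <- function(x, ...) {
  cat(sprintf("line_set: %d segment(s) in %s ROI\n", nrow(x$lines),
              x$source_roi$label))
  if (nrow(x$lines) > 0)
    print(utils::head(x$lines[, c("radius", "angle", "length", "votes")], 10))
  invisible(x)
}

#' Median of the detected line angles
#'
#' The median ignores outlier lines caused by the background; for an even
#' number of lines it is the arithmetic mean of the two middle values.
#'
#' @param line_set a [detect_lines()] result.
#' @return Median angle in degrees.
#' @export
median_angle <- function(line_set) {
  stopifnot(inherits(line_set, "line_set"))
  if (nrow(line_set$lines) == 0L)
    stop("no lines detected in ROI", call. = FALSE)
  stats::median(line_set$lines$angle)
}

#' Neck-shaft angle from femur and prosthesis line sets
#'
#' The NSA is the sum of the absolute values of the median femur angle and
#' the median prosthesis angle.
#'
#' @param femur_lines,prosthesis_lines non-empty [detect_lines()] results.
#' @param view `"AP"` or `"lateral"`.
#' @return An object of class `nsa_estimate`: list with
#'   `median_femur_angle`, `median_prosthesis_angle`, `nsa`, `view`.
#' @export
compute_nsa <- function(femur_lines, prosthesis_lines,
                        view = c("AP", "lateral")) {
  view <- match.arg(view)
  a_f <- median_angle(femur_lines)
  a_p <- median_angle(prosthesis_lines)
  structure(list(median_femur_angle = a_f, median_prosthesis_angle = a_p,
                 nsa = abs(a_f) + abs(a_p), view = view),
            class = "nsa_estimate")
}

#' @export
print.nsa_estimate <- function(x, ...) {
  cat(sprintf("NSA (%s view): %.2f deg  [femur %.2f, prosthesis %.2f]\n",
              x$view, x$nsa, x$median_femur_angle,
              x$median_prosthesis_angle))
  invisible(x)
}

#' Measure the NSA of a single radiograph
#'
#' Runs the full single-image chain: bilateral denoising, MSE template
#' matching, femur-region derivation, per-region Hough line detection, and
#' the median-angle NSA. The prosthesis ROI used for line detection is the
#' matched window padded by `roi_pad` pixels on the left, right, and top so
#' clipped stem edges are not lost, and by only `roi_pad_bottom` pixels at
#' the bottom, where the femoral shaft would otherwise intrude into the
#' prosthesis line set.
#'
#' @param image grayscale numeric matrix (0-255).
#' @param templates template bank, see [generate_template_bank()].
#' @param config a [nsa_config()] list.
#' @param view `"AP"` or `"lateral"`.
#' @return A list with the `nsa_estimate`, the `match_result`, and both
#'   ROIs.
#' @export
estimate_view_nsa <- function(image, templates, config = nsa_config(),
                              view = c("AP", "lateral")) {
  view <- match.arg(view)
  filtered <- bilateral_denoise(to_grayscale(image),
                                config$preprocess)
  match <- match_template(filtered, templates,
                          scales = config$detect$scales,
                          normalize = config$detect$normalize)
  pad <- config$detect$roi_pad
  pad_b <- config$detect$roi_pad_bottom
  pr <- match$roi
  x0 <- max(1L, pr$x - pad)
  y0 <- max(1L, pr$y - pad)
  pros_roi <- roi(x0, y0,
                  min(ncol(image) - x0 + 1L, pr$width + pad + (pr$x - x0)),
                  min(nrow(image) - y0 + 1L,
                      pr$height + pad_b + (pr$y - y0)),
                  "prosthesis")
  femur_roi <- derive_femur_roi(pr, nrow(image),
                                config$detect$extent_factor)
  femur_lines <- detect_lines(filtered, femur_roi, config$hough)
  pros_lines <- detect_lines(filtered, pros_roi, config$hough)
  est <- compute_nsa(femur_lines, pros_lines, view)
  list(estimate = est, match = match, prosthesis_roi = pros_roi,
       femur_roi = femur_roi, femur_lines = femur_lines,
       prosthesis_lines = pros_lines)
}

#' Split a cohort into tuning and evaluation subsets
#'
#' @param n_hips total number of hips.
#' @param fraction tuning fraction (default 0.3, i.e. 17 of 57).
#' @param seed integer seed for the shuffle.
#' @return List with integer index vectors `tuning` and `evaluation`.
#' @export
split_tuning <- function(n_hips, fraction = 0.3, seed = 1L) {
  if (n_hips < 1) stop("n_hips must be >= 1", call. = FALSE)
  n_tune <- max(1L, round(n_hips * fraction))
  ord <- with_seed(seed, sample.int(n_hips))
  list(tuning = sort(ord[seq_len(n_tune)]),
       evaluation = sort(ord[-seq_len(n_tune)]))
}

#' Tune Hough parameters on a set of synthetic scenes
#'
#' Grid-searches `min_line_length` and `vote_threshold`, scoring each
#' combination by the mean absolute NSA error of the full AP pipeline over
#' the tuning scenes (a scene on which detection fails contributes the
#' worst-case error of 180 degrees, so parameter sets that process every
#' scene are preferred). Ties resolve toward the larger `min_line_length`,
#' then the larger `vote_threshold`.
#'
#' @param tuning_scenes list of [generate_scene()] objects.
#' @param min_line_lengths,vote_thresholds numeric grids to search.
#' @param templates template bank; defaults to a fresh
#'   [generate_template_bank()].
#' @param config base [nsa_config()] whose other parameters are held fixed.
#' @return A list with `params` (the selected [hough_params()]), `error`
#'   (its mean absolute NSA error), and `grid` (per-combination scores).
#' @export
tune_hough <- function(tuning_scenes,
                       min_line_lengths = c(12, 15, 18, 22),
                       vote_thresholds = c(10, 15, 20, 25),
                       templates = generate_template_bank(),
                       config = nsa_config()) {
  if (length(tuning_scenes) < 1)
    stop("at least one tuning scene is required", call. = FALSE)
  grid <- expand.grid(min_line_length = min_line_lengths,
                      vote_threshold = vote_thresholds)
  grid$error <- NA_real_
  for (k in seq_len(nrow(grid))) {
    cfg <- config
    cfg$hough$min_line_length <- grid$min_line_length[k]
    cfg$hough$vote_threshold <- grid$vote_threshold[k]
    errs <- vapply(tuning_scenes, function(sc) {
      est <- tryCatch(
        estimate_view_nsa(sc$ap_image, templates, cfg, "AP")$estimate$nsa,
        error = function(e) NA_real_)
      if (is.na(est)) 180 else abs(est - sc$true_nsa_ap)
    }, numeric(1))
    grid$error[k] <- mean(errs)
  }
  if (all(grid$error >= 180))
    stop("all grid points fail on all tuning scenes", call. = FALSE)
  ord <- order(grid$error, -grid$min_line_length, -grid$vote_threshold)
  best <- grid[ord[1], ]
  hp <- config$hough
  hp$min_line_length <- best$min_line_length
  hp$vote_threshold <- best$vote_threshold
  list(params = hp, error = best$error, grid = grid)
}
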