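#' Axis-aligned region of interest
#'
#' @param x,y 1-based pixel column and row of the top-left corner.
#' @param width,height extent in pixels, both >= 1.
#' @param label one of `"prosthesis"` or `"femur"`.
#' @return An object of class `roi`.
#' @export
roi <- function(x, y, width, height, label = c("prosthesis", "femur")) {
  label <- match.arg(label)
  x <- as.integer(x); y <- as.integer(y)
  width <- as.integer(width); height <- as.integer(height)
  if (any(is.na(c(x, y, width, height))) || width < 1L || height < 1L ||
      x < 1L || y < 1L)
    stop("invalid ROI: x, y must be >= 1 and width, height >= 1",
         call. = FALSE)
  structure(list(x = x, y = y, width = width, height = height,
                 label = label), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi [%s]: x=%d y=%d %dx%d\n", x$label, x$x, x$y,
              x$width, x$height))
  invisible(x)
}

.check_roi_inside <- function(r, image) {
  if (r$x + r$width - 1L > ncol(image) || r$y + r$height - 1L > nrow(image))
    stop("ROI exceeds image bounds", call. = FALSE)
  invisible(r)
}

.crop <- function(image, r) {
  .check_roi_inside(r, image)
  image[r$y:(r$y + r$height - 1L), r$x:(r$x + r$width - 1L), drop = FALSE]
}

#' Mean squared intensity error between a window and a template
#'
#' @param window,template equal-sized grayscale matrices.
#' @return Mean over pixels of the squared intensity difference
#'   (intensity^2 units); 0 exactly when the arrays are identical.
#' @export
mse_score <- function(window, template) {
  stop_if_not_image(window, "window")
  stop_if_not_image(template, "template")
  if (!identical(dim(window), dim(template)))
    stop("window and template dimensions differ", call. = FALSE)
  mse_cpp(window, template)
}

# nearest-neighbor resize by a positive scale factor
.resize_nn <- function(img, scale) {
  h2 <- max(1L, as.integer(round(nrow(img) * scale)))
  w2 <- max(1L, as.integer(round(ncol(img) * scale)))
  ri <- pmin(nrow(img), floor((seq_len(h2) - 0.5) * nrow(img) / h2) + 1)
  ci <- pmin(ncol(img), floor((seq_len(w2) - 0.5) * ncol(img) / w2) + 1)
  img[ri, ci, drop = FALSE]
}

#' Locate the prosthesis by exhaustive MSE template matching
#'
#' Slides every template, at every scale in `scales`, over every valid
#' window position (stride 1) and returns the placement minimizing the
#' mean squared intensity error. Templates are scanned in bank order,
#' scales in increasing order within a template, and window positions
#' row-major; the global best is updated only on a strict improvement, so
#' ties resolve to the first placement encountered, then the lower template
#' index, then the smaller scale. With `normalize = TRUE` both window and
#' template are compared zero-mean (for real images whose absolute
#' intensity calibration differs from the bank's).
#'
#' @param image grayscale numeric matrix.
#' @param templates list of grayscale template matrices.
#' @param scales numeric vector of scale factors applied to each template.
#' @param normalize compare intensities zero-mean rather than raw.
#' @return An object of class `match_result`: list with `roi` (the matched
#'   window, label `"prosthesis"`), `template_index`, `scale`, and `mse`.
#' @export
match_template <- function(image, templates, scales = c(0.8, 1, 1.25),
                           normalize = FALSE) {
  stop_if_not_image(image)
  if (!is.list(templates) || length(templates) == 0L)
    stop("`templates` must be a non-empty list of matrices", call. = FALSE)
  scales <- sort(scales)
  if (any(scales <= 0)) stop("scales must be positive", call. = FALSE)

  scaled <- list()
  meta <- list()
  for (ti in seq_along(templates)) {
    for (s in scales) {
      tpl <- .resize_nn(templates[[ti]], s)
      if (nrow(tpl) > nrow(image) || ncol(tpl) > ncol(image)) next
      scaled[[length(scaled) + 1L]] <-
        if (normalize) tpl - mean(tpl) else tpl
      meta[[length(meta) + 1L]] <- list(template_index = ti, scale = s)
    }
  }
  if (length(scaled) == 0L)
    stop("no template fits inside the image at any scale", call. = FALSE)

  img <- if (normalize) image - mean(image) else image
  res <- match_template_cpp(img, scaled, prepass_stride = 4L)
  if (res$template == 0L)
    stop("no valid template placement", call. = FALSE)
  m <- meta[[res$template]]
  tpl <- scaled[[res$template]]
  structure(list(
    roi = roi(res$x, res$y, ncol(tpl), nrow(tpl), "prosthesis"),
    template_index = m$template_index,
    scale = m$scale,
    mse = res$mse), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: template %d @ scale %.2f, mse %.3f\n",
              x$template_index, x$scale, x$mse))
  print(x$roi)
  invisible(x)
}

#' Derive the femur region below a detected prosthesis
#'
#' The femur region is the area under the lower side of the detected
#' prosthesis: same columns, starting at the prosthesis bottom edge, with
#' height `extent_factor` times the prosthesis height, clipped to the
#' image.
#'
#' @param prosthesis_roi a [roi()] for the prosthesis.
#' @param image_height image height in pixels.
#' @param extent_factor femur height as a multiple of the prosthesis
#'   height.
#' @return A [roi()] labelled `"femur"`.
#' @export
derive_femur_roi <- function(prosthesis_roi, image_height,
                             extent_factor = 2) {
  stopifnot(inherits(prosthesis_roi, "roi"))
  if (extent_factor <= 0) stop("extent_factor must be positive",
                               call. = FALSE)
  top <- prosthesis_roi$y + prosthesis_roi$height
  if (top > image_height)
    stop("no space below the prosthesis: femur undetectable", call. = FALSE)
  h <- min(round(extent_factor * prosthesis_roi$height),
           image_height - top + 1L)
  roi(prosthesis_roi$x, top, prosthesis_roi$width, h, "femur")
}
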