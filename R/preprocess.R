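#' Bilateral filter parameters
#'
#' @param diameter odd neighborhood diameter in pixels, >= 3.
#' @param sigma_color intensity-domain standard deviation (0-255 units).
#' @param sigma_space spatial-domain standard deviation in pixels.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(diameter = 9, sigma_color = 50, sigma_space = 5) {
  diameter <- as.integer(diameter)
  if (is.na(diameter) || diameter < 3L || diameter %% 2L == 0L)
    stop("`diameter` must be an odd integer >= 3", call. = FALSE)
  if (!is.finite(sigma_color) || sigma_color <= 0 ||
      !is.finite(sigma_space) || sigma_space <= 0)
    stop("`sigma_color` and `sigma_space` must be positive", call. = FALSE)
  structure(list(diameter = diameter, sigma_color = sigma_color,
                 sigma_space = sigma_space), class = "filter_params")
}

#' Convert an image to grayscale
#'
#' Color input (a height x width x 3 array) is collapsed with the Rec. 601
#' luminance weights 0.299 R + 0.587 G + 0.114 B; an already-gray matrix
#' passes through unchanged.
#'
#' @param image a numeric matrix or height x width x channels array.
#' @return A numeric matrix with the same spatial dimensions.
#' @export
to_grayscale <- function(image) {
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) == 3L && d[3] == 1L) return(image[, , 1])
  if (length(d) != 3L || d[3] > 3L)
    stop("image must be 2-D or have at most 3 channels", call. = FALSE)
  if (d[3] == 2L) stop("2-channel images are not supported", call. = FALSE)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Edge-preserving bilateral denoising
#'
#' Smooths background noise while preserving high-contrast edges by
#' weighting each neighbor with the product of a spatial Gaussian
#' (`sigma_space`) and an intensity-similarity Gaussian (`sigma_color`).
#' Borders are handled by reflect padding, which avoids the dark-border
#' artifacts that would otherwise seed spurious Hough lines. The output is
#' a convex combination of input intensities, so it stays within the input
#' range, and a constant image is returned unchanged.
#'
#' @param image grayscale numeric matrix (0-255 scale).
#' @param params a [filter_params()] object.
#' @return Filtered matrix of the same dimensions.
#' @export
bilateral_denoise <- function(image, params = filter_params()) {
  stop_if_not_image(image)
  stopifnot(inherits(params, "filter_params"))
  bilateral_cpp(image, params$diameter, params$sigma_color,
                params$sigma_space)
}
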