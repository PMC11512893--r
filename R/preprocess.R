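#' Median-filter denoising
#'
#' Replaces each pixel by the median of an odd square neighbourhood window
#' centred on it, the classic nonlinear denoiser for salt-and-pepper
#' (impulse) noise in CT slices.  Borders are handled by edge replication,
#' so a constant image is a fixed point of the filter.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param window odd window side length, `>= 3` and at most the smaller
#'   image dimension.
#' @return filtered matrix of the same dimensions; the output range is a
#'   subset of the input range (the median is a selection statistic).
#' @export
#' @examples
#' x <- matrix(c(1, 2, 3, 4, 100, 6, 7, 8, 9) / 100, 3, 3, byrow = TRUE)
#' median_filter(x, 3)[2, 2] * 100  # 6, the median of the nine values
median_filter <- function(image, window = 3L) {
  check_gray_image(image)
  if (!is.numeric(window) || length(window) != 1 || window %% 2 != 1 ||
      window < 3 || window > min(dim(image)))
    stop_arg("window must be an odd integer in [3, %d], got %s",
             min(dim(image)), format(window))
  cpp_median_filter(image, as.integer(window))
}
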