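#' @title Frame preprocessing
#'
#' @description
#' Ultrasound B-mode frames carry multiplicative speckle and low contrast.
#' Before level-set segmentation each frame is (1) contrast-enhanced by
#' global histogram equalization and (2) despeckled with a median filter,
#' in that order. The median filter suppresses speckle while keeping the
#' edge structure the region forces depend on.
#'
#' @name preprocess
NULL

#' Global histogram equalization
#'
#' Remaps intensities over 256 bins so that they spread across the full
#' `[0, 255]` range. The mapping used is `v -> round(255 * cdf(v))` with the
#' empirical CDF over integer-rounded input intensities; it is monotone
#' non-decreasing by construction.
#'
#' @param img numeric matrix, intensities in `[0, 255]`.
#' @return equalized image, same dimensions, integer-valued in `[0, 255]`.
#' @export
equalize_histogram <- function(img) {
  assert_grey_image(img)
  v <- round(img)
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(v)
  lut <- round(255 * cdf)
  matrix(lut[as.integer(v) + 1L], nrow(img), ncol(img))
}

#' Median filter with reflected borders
#'
#' Per-pixel median over a `kernel x kernel` window; borders handled by
#' reflection.
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param kernel odd window side, at least 3.
#' @return filtered image, same dimensions.
#' @export
median_filter <- function(img, kernel = 5L) {
  assert_grey_image(img)
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L)
    stop("kernel must be an odd integer >= 3, got ", kernel)
  r <- (kernel - 1L) %/% 2L
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  stack <- vapply(seq_len(nrow(offs)),
                  function(i) as.vector(shift_reflect(img, offs$dr[i], offs$dc[i])),
                  numeric(length(img)))
  med <- apply(stack, 1, median)
  matrix(med, nrow(img), ncol(img))
}

#' Preprocess one frame
#'
#' Histogram equalization followed by median filtering.
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param cfg list with `enabled` (logical, applies the median filter;
#'   default TRUE) and `median_kernel` (odd int, default 5).
#' @return preprocessed image.
#' @export
preprocess_frame <- function(img, cfg = list()) {
  enabled <- if (is.null(cfg$enabled)) TRUE else isTRUE(cfg$enabled)
  kernel <- if (is.null(cfg$median_kernel)) 5L else cfg$median_kernel
  out <- equalize_histogram(img)
  if (enabled) out <- median_filter(out, kernel)
  out
}
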