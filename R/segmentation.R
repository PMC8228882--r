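#' Intensity histogram restricted to the breast mask
#'
#' Tallies the 256 intensity levels of the in-mask pixels. Restricting the
#' histogram to the mask keeps the cropped black background from dominating
#' the low-intensity class when thresholding; `scope = "frame"` reproduces
#' whole-frame histogramming for comparison.
#'
#' @param image Grayscale image matrix (integer values 0-255).
#' @param mask Breast mask (logical matrix); ignored when `scope = "frame"`.
#' @param scope `"mask"` (default) or `"frame"`.
#' @return A `histogram256`: `$counts` (length-256 integer vector, level i
#'   at index i + 1) and `$total`.
#' @export
masked_histogram <- function(image, mask, scope = c("mask", "frame")) {
  scope <- match.arg(scope)
  assert_gray_image(image)
  vals <- if (scope == "frame") {
    as.vector(image)
  } else {
    mask <- as_mask_pixels(mask)
    assert_same_shape(image, mask)
    if (!any(mask)) stop("empty mask: no pixels to histogram", call. = FALSE)
    image[mask]
  }
  counts <- tabulate(as.integer(vals) + 1L, nbins = 256L)
  structure(list(counts = counts, total = sum(counts)),
            class = "histogram256")
}

#' Maximum-entropy (Kapur) threshold of a 256-bin histogram
#'
#' Returns the intensity level t maximizing the summed Shannon entropies of
#' the two classes the threshold induces,
#' \deqn{\psi(t) = H_{low}(t) + H_{high}(t),}
#' where with \eqn{p_i = counts_i / total} and \eqn{P_t = \sum_{i \le t} p_i},
#' \eqn{H_{low} = -\sum_{i \le t} (p_i/P_t)\log(p_i/P_t)} and
#' \eqn{H_{high} = -\sum_{i > t} (p_i/(1-P_t))\log(p_i/(1-P_t))}, natural
#' logarithms, zero-probability bins skipped. Candidates are the levels with
#' mass on both sides (0 < P_t < 1); ties are broken toward the smallest
#' level so the result is deterministic.
#'
#' @param hist A [masked_histogram()] result (or a length-256 count vector).
#' @return Integer threshold in 0-254; pixels strictly above it form the
#'   dense (high) class.
#' @export
kapur_threshold <- function(hist) {
  counts <- if (inherits(hist, "histogram256")) hist$counts else hist
  if (length(counts) != 256L || any(counts < 0)) {
    stop("expected 256 nonnegative bin counts", call. = FALSE)
  }
  if (sum(counts > 0) < 2L) {
    stop("histogram needs at least two distinct nonzero bins to split",
         call. = FALSE)
  }
  total <- sum(counts)
  p <- counts / total
  plogp <- ifelse(p > 0, p * log(p), 0)
  cum_n <- cumsum(counts)          # pixels at levels <= t, index t + 1
  P <- cum_n / total
  S <- cumsum(-plogp)              # partial entropy sums
  S_all <- S[256L]
  t_all <- 0:254
  valid <- cum_n[t_all + 1L] > 0 & cum_n[t_all + 1L] < total
  psi <- rep(-Inf, 255L)
  Pv <- P[t_all + 1L][valid]
  Sv <- S[t_all + 1L][valid]
  psi[valid] <- Sv / Pv + log(Pv) + (S_all - Sv) / (1 - Pv) + log(1 - Pv)
  t_all[which.max(psi)]            # which.max takes the smallest on ties
}

#' Threshold the masked image into a dense-tissue map
#'
#' A pixel is radiodense iff it lies in the breast mask and its intensity is
#' strictly greater than the threshold (the threshold level itself belongs
#' to the lower, radiolucent class).
#'
#' @param image Grayscale image matrix.
#' @param mask Breast mask (logical matrix).
#' @param t Intensity threshold in 0-254, e.g. from [kapur_threshold()].
#' @return A `dense_map`: `$pixels` (logical matrix) and `$threshold`.
#' @export
segment <- function(image, mask, t) {
  assert_gray_image(image)
  mask <- as_mask_pixels(mask)
  assert_same_shape(image, mask)
  if (t < 0 || t > 254) stop("threshold must lie in [0, 254]", call. = FALSE)
  structure(list(pixels = mask & image > t, threshold = as.integer(t)),
            class = "dense_map")
}

#' Overall percent density
#'
#' The headline mammographic-density figure: 100 x dense pixel count /
#' breast-mask pixel count, i.e. the white (radiodense) share of the defined
#' breast area after segmentation.
#'
#' @param dense Dense map ([segment()] result or logical matrix).
#' @param mask Breast mask (logical matrix, nonempty).
#' @return Percentage in \[0, 100\].
#' @export
overall_pd <- function(dense, mask) {
  dense <- as_mask_pixels(dense)
  mask <- as_mask_pixels(mask)
  assert_same_shape(dense, mask)
  n <- sum(mask)
  if (n == 0) stop("empty mask: overall PD undefined", call. = FALSE)
  100 * sum(dense & mask) / n
}
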