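#' Rasterize breast / pectoral ROI polygons into a breast mask
#'
#' Converts a manually delineated region of interest into the binary breast
#' mask used by all downstream stages: pixels whose centres fall inside the
#' breast polygon and outside the pectoral polygon. Coordinates follow the
#' package-wide convention: origin at the top-left corner, x along columns,
#' y along rows, 0-based, so pixel (row r, col c) (0-based) has centre
#' (c + 0.5, r + 0.5). Containment is tested at pixel centres.
#'
#' @param image A grayscale image matrix (only its shape is used).
#' @param breast Breast-contour polygon: a matrix/data frame with columns
#'   `x`, `y` (>= 3 vertices, in pixel coordinates).
#' @param pectoral Optional pectoral-muscle polygon to subtract.
#' @return Logical matrix of the image shape.
#' @export
polygon_to_mask <- function(image, breast, pectoral = NULL) {
  h <- nrow(image); w <- ncol(image)
  inside <- function(poly) {
    poly <- as.matrix(poly[, c("x", "y")])
    if (nrow(poly) < 3) stop("a polygon needs at least 3 vertices",
                             call. = FALSE)
    if (any(poly[, "x"] < 0 | poly[, "x"] > w |
            poly[, "y"] < 0 | poly[, "y"] > h)) {
      stop("polygon vertices fall outside the image bounds", call. = FALSE)
    }
    cx <- rep(seq_len(w) - 0.5, each = h)
    cy <- rep(seq_len(h) - 0.5, times = w)
    matrix(pracma::inpolygon(cx, cy, poly[, "x"], poly[, "y"]), h, w)
  }
  mask <- inside(breast)
  if (!is.null(pectoral)) mask <- mask & !inside(pectoral)
  if (!any(mask)) {
    stop("degenerate ROI: breast polygon minus pectoral polygon covers no pixel centres",
         call. = FALSE)
  }
  mask
}

#' Read an ROI polygon from CSV
#'
#' Expects columns `x`, `y` (pixel coordinates, one vertex per row) and
#' optionally `label` (`breast` or `pectoral`, constant per file).
#'
#' @param path CSV file path.
#' @return Data frame with `x`, `y` and a `label` attribute.
#' @export
read_polygon_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) {
    stop("polygon CSV must have columns x and y", call. = FALSE)
  }
  lab <- if ("label" %in% names(df)) as.character(df$label[1]) else "breast"
  out <- df[, c("x", "y")]
  attr(out, "label") <- lab
  out
}

#' Linear contrast stretch within the breast mask
#'
#' Rescales in-mask intensities linearly so that `saturated_fraction` of the
#' mask pixels saturate at each end (at 0 and at 255); off-mask pixels are
#' untouched and the output is rounded and clipped to \[0, 255\]. Intended as
#' a contour-outlining aid near the thin skin border; the segmentation path
#' does not apply it by default.
#'
#' @param image Grayscale image matrix.
#' @param mask Breast mask (logical matrix).
#' @param saturated_fraction Fraction saturated at each end, in \[0, 0.5).
#'   Default 0.0035, the usual interactive contrast-stretch default.
#' @return Image matrix of the same shape.
#' @export
enhance_contrast <- function(image, mask, saturated_fraction = 0.0035) {
  assert_gray_image(image)
  mask <- as_mask_pixels(mask)
  assert_same_shape(image, mask)
  if (saturated_fraction < 0 || saturated_fraction >= 0.5) {
    stop("saturated_fraction must lie in [0, 0.5)", call. = FALSE)
  }
  vals <- image[mask]
  lo <- as.numeric(stats::quantile(vals, saturated_fraction, type = 1))
  hi <- as.numeric(stats::quantile(vals, 1 - saturated_fraction, type = 1))
  if (hi <= lo) {
    warning("constant in-mask image: contrast enhancement is a no-op")
    return(image)
  }
  out <- image
  out[mask] <- round(pmin(pmax((vals - lo) * 255 / (hi - lo), 0), 255))
  storage.mode(out) <- "integer"
  out
}

#' Zero out everything outside the breast mask
#'
#' Crops the image to the region of interest by setting off-mask pixels to 0
#' (so radiodense structures outside the contour cannot contaminate density
#' quantification); in-mask pixels are unchanged. Idempotent.
#'
#' @param image Grayscale image matrix.
#' @param mask Breast mask (logical matrix, same shape).
#' @return Image matrix of the same shape.
#' @export
apply_mask <- function(image, mask) {
  mask <- as_mask_pixels(mask)
  assert_same_shape(image, mask)
  image[!mask] <- 0L
  image
}
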