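#' Spatial weight matrix over grid tiles
#'
#' Builds the tile-pair weight matrix used by [morans_i()]. The default
#' scheme weights every ordered tile pair by the inverse square of the
#' Euclidean distance between tile midpoints, measured in tile units (two
#' horizontally adjacent midpoints are distance 1). Contiguity alternatives
#' are provided because "adjacent sub-regions" weighting is a common variant:
#' `rook` weights edge neighbours (distance 1) with 1, `queen` additionally
#' weights diagonal neighbours with 1/2 (their squared distance is 2); both
#' are the inverse-square-distance weights restricted to those neighbours.
#'
#' @param grid A [make_grid()] layout (>= 2 tiles).
#' @param scheme `"inverse_distance_squared"` (default), `"rook"`, or
#'   `"queen"`.
#' @return An N x N matrix (N = number of tiles, row-major tile order) with a
#'   zero diagonal and attribute `scheme`.
#' @examples
#' W <- weight_matrix(make_grid(96, 72))
#' W[1, 2]        # horizontally adjacent: 1
#' W[1, 8]        # diagonal neighbour: 1/2
#' @export
weight_matrix <- function(grid,
                          scheme = c("inverse_distance_squared", "rook",
                                     "queen")) {
  scheme <- match.arg(scheme)
  n <- grid$rows * grid$cols
  if (n < 2L) stop("grid must have at least 2 tiles", call. = FALSE)
  rr <- rep(grid$mid_row, each = grid$cols)
  cc <- rep(grid$mid_col, times = grid$rows)
  d2 <- outer(rr, rr, "-")^2 + outer(cc, cc, "-")^2
  w <- matrix(0, n, n)
  off <- d2 > 0
  if (scheme == "inverse_distance_squared") {
    w[off] <- 1 / d2[off]
  } else {
    w[abs(d2 - 1) < 1e-9] <- 1
    if (scheme == "queen") w[abs(d2 - 2) < 1e-9] <- 0.5
  }
  attr(w, "scheme") <- scheme
  w
}

#' Moran's I spatial autocorrelation of regional percent densities
#'
#' Computes the global Moran's I statistic
#' \deqn{I = \frac{N}{\sum_i\sum_j w_{ij}} \cdot
#'   \frac{\sum_i\sum_j w_{ij}(x_i-\bar x)(x_j-\bar x)}
#'        {\sum_i (x_i-\bar x)^2}}
#' over the tile values, with the double sums running over all ordered pairs
#' (the zero diagonal removes i = j terms). Positive I means similar values
#' sit near each other (clustered), negative means dissimilar values are
#' interspersed (scattered). For practical inputs I lies in roughly [-1, 1].
#'
#' @param values Regional PDs: a numeric vector in row-major tile order, or a
#'   rows x cols matrix (e.g. `$pd` of [regional_pd()]), or a `density_grid`.
#' @param W Weight matrix from [weight_matrix()]; if `NULL`, the default
#'   inverse-square-distance weights for an 8 x 6 grid (or the grid carried
#'   by a `density_grid` input) are used.
#' @param eps Tolerance handed to [classify_pattern()].
#' @return A `moran_result`: `$I`, `$N`, `$pattern`, `$x_bar`, `$scheme`.
#' @export
morans_i <- function(values, W = NULL, eps = 0) {
  grid <- NULL
  if (inherits(values, "density_grid")) {
    grid <- values$grid
    values <- values$pd
  }
  if (is.matrix(values)) values <- as.vector(t(values))  # row-major order
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must be finite", call. = FALSE)
  if (is.null(W)) {
    if (is.null(grid)) grid <- make_grid(8L, 6L, 8L, 6L)
    W <- weight_matrix(grid)
  }
  n <- length(values)
  if (!is.matrix(W) || any(dim(W) != n)) {
    stop(sprintf("weight matrix must be %dx%d", n, n), call. = FALSE)
  }
  dev <- values - mean(values)
  ss <- sum(dev^2)
  if (ss == 0) stop("Moran's I undefined for constant field", call. = FALSE)
  s0 <- sum(W)
  i_stat <- (n / s0) * drop(crossprod(dev, W %*% dev)) / ss
  structure(list(I = i_stat, N = n,
                 pattern = classify_pattern(i_stat, eps = eps),
                 x_bar = mean(values),
                 scheme = attr(W, "scheme") %||% "custom"),
            class = "moran_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f over N = %d tiles (%s weights): %s pattern\n",
              x$I, x$N, x$scheme, x$pattern))
  invisible(x)
}

#' Classify a spatial pattern from Moran's I
#'
#' Sign rule: positive autocorrelation is a clustered spatial pattern,
#' (near-)zero is random, negative is scattered. `eps` widens the "random"
#' band for floating-point robustness; the default 0 is the strict sign rule.
#'
#' @param I Moran's I statistic (finite).
#' @param eps Half-width of the band classified as `random`.
#' @return One of `"clustered"`, `"random"`, `"scattered"`.
#' @export
classify_pattern <- function(I, eps = 0) {
  if (!is.finite(I)) stop("Moran's I must be finite", call. = FALSE)
  if (I > eps) "clustered" else if (I < -eps) "scattered" else "random"
}
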