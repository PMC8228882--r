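#' Partition an image frame into an 8 x 6 tile grid
#'
#' Divides a `height` x `width` pixel frame into `rows` x `cols` rectangular
#' tiles (default the 48-tile layout used for regional percent-density work).
#' Tile heights and widths differ by at most one pixel; when the dimension is
#' not divisible, the remainder pixels are assigned to the last tiles along
#' that axis. Tiles partition the frame exactly.
#'
#' @param height,width Frame size in pixels.
#' @param rows,cols Grid shape; defaults 8 rows x 6 columns.
#' @return A `tile_grid` object: row/col pixel breakpoints (0-based, half-open
#'   intervals), per-tile midpoints in tile units (index + 0.5), and the grid
#'   shape. Tiles are numbered row-major, top-left first.
#' @examples
#' g <- make_grid(480, 360)
#' diff(g$row_breaks)   # all 60
#' @export
make_grid <- function(height, width, rows = 8L, cols = 6L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (height < rows || width < cols) {
    stop(sprintf("image (%dx%d) smaller than grid (%dx%d)",
                 height, width, rows, cols), call. = FALSE)
  }
  axis_sizes <- function(n, k) {
    base <- n %/% k; rem <- n %% k
    c(rep(base, k - rem), rep(base + 1L, rem))
  }
  rh <- axis_sizes(as.integer(height), rows)
  cw <- axis_sizes(as.integer(width), cols)
  structure(list(
    rows = rows, cols = cols, height = as.integer(height),
    width = as.integer(width),
    row_breaks = c(0L, cumsum(rh)),   # tile r spans [row_breaks[r], row_breaks[r+1])
    col_breaks = c(0L, cumsum(cw)),
    mid_row = seq_len(rows) - 0.5,    # midpoints in tile units
    mid_col = seq_len(cols) - 0.5
  ), class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %dx%d tiles over a %dx%d frame\n",
              x$rows, x$cols, x$height, x$width))
  invisible(x)
}

# Tile index (row-major, 1-based) of every pixel; h x w integer matrix.
tile_index_matrix <- function(grid) {
  row_tile <- rep.int(seq_len(grid$rows), diff(grid$row_breaks))
  col_tile <- rep.int(seq_len(grid$cols), diff(grid$col_breaks))
  outer(row_tile, col_tile, function(r, c) (r - 1L) * grid$cols + c)
}

#' Regional percent density over a tile grid
#'
#' Computes the percent density of each tile of an 8 x 6 grid from a binary
#' dense-tissue map. With `denominator = "tile"` each tile's PD is
#' 100 * dense pixels / tile area (background counts as non-dense, matching a
#' plain tile split of the segmented image); with `denominator = "mask"` the
#' denominator is the number of in-breast pixels in the tile, and tiles with
#' no breast coverage report PD 0 with denominator 0.
#'
#' @param dense Dense-tissue map: logical matrix or a [segment()] result.
#' @param mask Breast mask, logical matrix (used by `denominator = "mask"`).
#' @param grid A [make_grid()] layout matching the image frame.
#' @param denominator `"tile"` (default) or `"mask"`.
#' @return A `density_grid`: `$pd` (rows x cols matrix of percentages),
#'   `$denominators` (pixel counts), `$grid`.
#' @export
regional_pd <- function(dense, mask, grid = NULL,
                        denominator = c("tile", "mask")) {
  denominator <- match.arg(denominator)
  dense <- as_mask_pixels(dense)
  mask <- as_mask_pixels(mask)
  assert_same_shape(dense, mask)
  if (is.null(grid)) grid <- make_grid(nrow(dense), ncol(dense))
  if (nrow(dense) != grid$height || ncol(dense) != grid$width) {
    stop("dense map shape does not match the grid frame", call. = FALSE)
  }
  n_tiles <- grid$rows * grid$cols
  idx <- tile_index_matrix(grid)
  dense_ct <- tabulate(idx[dense], nbins = n_tiles)
  denom <- if (denominator == "tile") {
    tabulate(idx, nbins = n_tiles)
  } else {
    tabulate(idx[mask], nbins = n_tiles)
  }
  pd <- ifelse(denom > 0, 100 * dense_ct / denom, 0)
  shape <- function(v) matrix(v, grid$rows, grid$cols, byrow = TRUE)
  structure(list(pd = shape(pd), denominators = shape(denom),
                 grid = grid, denominator = denominator),
            class = "density_grid")
}

#' Default posterior/middle/anterior zone definition
#'
#' Splits the six grid columns into three contiguous two-column bands along
#' the chest-wall-to-nipple axis: the two columns nearest the chest wall form
#' the posterior zone, the middle two the middle zone, and the outermost two
#' the anterior zone.
#'
#' @param chest_wall Which image edge the chest wall touches: `"left"`
#'   (the MLO default here) or `"right"`.
#' @param cols Number of grid columns (must be divisible by 3).
#' @return A `zone_definition`: a character vector mapping each column to a
#'   zone, plus the chest-wall side.
#' @export
default_zones <- function(chest_wall = c("left", "right"), cols = 6L) {
  chest_wall <- match.arg(chest_wall)
  if (cols %% 3L != 0L) stop("cols must be divisible by 3", call. = FALSE)
  band <- cols %/% 3L
  z <- rep(c("posterior", "middle", "anterior"), each = band)
  if (chest_wall == "right") z <- rev(z)
  structure(list(zones = z, chest_wall = chest_wall),
            class = "zone_definition")
}

#' Zonal percent density
#'
#' Averages the regional PDs of a [regional_pd()] grid within each zone of a
#' [default_zones()] definition (unweighted arithmetic mean over the zone's
#' tiles, e.g. 16 tiles per zone in the 8 x 6 / 2-column-band default).
#'
#' @param dgrid A `density_grid`.
#' @param zones A `zone_definition` covering all grid columns.
#' @return Named numeric vector with components `posterior`, `middle`,
#'   `anterior` (percentages).
#' @export
zonal_pd <- function(dgrid, zones = default_zones()) {
  if (!inherits(dgrid, "density_grid")) stop("dgrid must be a density_grid",
                                             call. = FALSE)
  if (length(zones$zones) != ncol(dgrid$pd)) {
    stop("zone definition does not cover all grid columns", call. = FALSE)
  }
  vapply(c(posterior = "posterior", middle = "middle", anterior = "anterior"),
         function(z) mean(dgrid$pd[, zones$zones == z]), numeric(1))
}
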