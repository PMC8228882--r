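#' Read / write 8-bit grayscale images and binary masks as PNG
#'
#' `read_gray_png()` returns an integer matrix with values 0-255 (multi-
#' channel PNGs are collapsed to their first channel); `write_gray_png()`
#' writes one. `read_mask_png()` / `write_mask_png()` do the same for
#' binary masks (nonzero = TRUE).
#'
#' @param path PNG file path.
#' @return `read_gray_png()`: integer matrix; `read_mask_png()`: logical
#'   matrix; the writers return `path` invisibly.
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  m <- round(x * 255)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_gray_png
#' @param image Integer matrix, values 0-255.
#' @export
write_gray_png <- function(image, path) {
  assert_gray_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname read_gray_png
#' @export
read_mask_png <- function(path) {
  read_gray_png(path) > 127
}

#' @rdname read_gray_png
#' @param mask Logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_mask_pixels(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Export a phantom cohort to disk
#'
#' Writes each subject's image, breast mask and ground-truth dense mask as
#' PNGs under `dir`, plus a `metadata.csv` with id, age, BI-RADS group,
#' planted fraction, placement and seed.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "phantom_cohort")) {
    stop("cohort must be a phantom_cohort", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$id[i]
    ph <- cohort$phantoms[[i]]
    write_gray_png(ph$image, file.path(dir, paste0(id, "_image.png")))
    write_mask_png(ph$breast_mask, file.path(dir, paste0(id, "_breast.png")))
    write_mask_png(ph$true_dense_mask, file.path(dir, paste0(id, "_dense.png")))
  }
  utils::write.csv(cohort$subjects, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Render a regional PD matrix as a heatmap
#'
#' Plots an 8 x 6 regional PD matrix with the conventional density hues:
#' yellow for no / minimal density, orange around 25%, red at 50% and above,
#' with the per-tile PD value printed in each cell. Writes a PNG when `file`
#' is given, otherwise draws on the current device.
#'
#' @param pd Matrix of regional PD percentages (or a `density_grid`).
#' @param main Plot title.
#' @param file Optional PNG output path.
#' @return The input matrix, invisibly.
#' @export
plot_pd_heatmap <- function(pd, main = "Regional percent density",
                            file = NULL) {
  if (inherits(pd, "density_grid")) pd <- pd$pd
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 760)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  pal <- grDevices::colorRampPalette(c("yellow", "orange", "red"))(100)
  capped <- pmin(pd, 50)                 # >= 50% saturates at full red
  nr <- nrow(pd); nc <- ncol(pd)
  graphics::image(x = seq_len(nc), y = seq_len(nr),
                  z = t(capped[nr:1, , drop = FALSE]),
                  zlim = c(0, 50), col = pal, axes = FALSE,
                  xlab = "column (chest wall to nipple)", ylab = "row",
                  main = main)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    graphics::text(c, nr - r + 1, sprintf("%.1f", pd[r, c]), cex = 0.9)
  }
  graphics::box()
  invisible(pd)
}
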