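#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so phantom generation never perturbs user RNG flow.
with_preserved_seed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

assert_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (any(image < 0 | image > 255)) {
    stop("image intensities must lie in [0, 255]", call. = FALSE)
  }
  invisible(image)
}

assert_same_shape <- function(a, b, what = "mask") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s dimensions (%s) do not match image dimensions (%s)",
                 what, paste(dim(b), collapse = "x"),
                 paste(dim(a), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

# Accept either a logical matrix or a dense_map / object carrying $pixels.
as_mask_pixels <- function(x) {
  if (is.list(x) && !is.null(x$pixels)) x <- x$pixels
  if (!is.matrix(x)) stop("expected a logical matrix (or an object with $pixels)",
                          call. = FALSE)
  if (!is.logical(x)) storage.mode(x) <- "logical"
  x
}
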