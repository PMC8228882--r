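#' Specification of a synthetic MLO-view breast phantom
#'
#' Bundles and validates the parameters of [generate_phantom()]. The phantom
#' emulates a mediolateral-oblique mammogram at desk scale: a half-elliptical
#' breast region touching the chest-wall image edge, a triangular pectoral
#' cut-out at the top chest-wall corner, dark adipose background inside the
#' breast, bright fibroglandular blobs with a controllable total dense
#' fraction and placement, and additive Gaussian noise, emitted as a valid
#' 8-bit raster together with ground-truth breast and dense masks.
#'
#' @param image_height,image_width Frame size in pixels (each >= 48).
#' @param dense_fraction Target fraction of breast-mask area that is
#'   radiodense, in \[0, 1\].
#' @param blob_count Number of fibroglandular blob seeds (>= 1).
#' @param placement One of `"posterior"`, `"middle"`, `"anterior"` (blob
#'   centres confined to that zone of the default 8 x 6 grid), `"uniform"`
#'   (centres anywhere in the breast), or `"checkerboard"` (dense tissue on
#'   alternating grid tiles, a planted scattered/negative-autocorrelation
#'   pattern).
#' @param dense_level,adipose_level Mean intensities (0-255) of dense and
#'   adipose tissue; `adipose_level < dense_level`.
#' @param noise_sd Gaussian noise standard deviation in intensity units,
#'   applied inside the breast mask only.
#' @param seed Integer RNG seed; identical spec + seed is bit-reproducible.
#' @param chest_wall Image edge the chest wall touches (`"left"` or
#'   `"right"`).
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(image_height = 160L, image_width = 128L,
                         dense_fraction = 0.2, blob_count = 4L,
                         placement = c("uniform", "posterior", "middle",
                                       "anterior", "checkerboard"),
                         dense_level = 200, adipose_level = 80,
                         noise_sd = 10, seed = 1L,
                         chest_wall = c("left", "right")) {
  placement <- match.arg(placement)
  chest_wall <- match.arg(chest_wall)
  if (image_height < 48 || image_width < 48) {
    stop("phantom image must be at least 48x48 pixels", call. = FALSE)
  }
  if (dense_fraction < 0 || dense_fraction > 1) {
    stop("dense_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (blob_count < 1) stop("blob_count must be positive", call. = FALSE)
  if (adipose_level >= dense_level) {
    stop("adipose_level must be below dense_level", call. = FALSE)
  }
  if (dense_level > 255 || adipose_level < 0) {
    stop("tissue levels must lie in [0, 255]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 dense_fraction = dense_fraction,
                 blob_count = as.integer(blob_count),
                 placement = placement,
                 dense_level = dense_level, adipose_level = adipose_level,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 chest_wall = chest_wall),
            class = "phantom_spec")
}

# Breast mask geometry shared by all phantoms of one frame size: half-ellipse
# clipped at the chest-wall edge minus a corner triangle for the pectoral
# muscle (kept under ~15% of the breast area). Pixel (r, c) has centre
# (x, y) = (c - 0.5, r - 0.5) with the origin at the top-left corner.
phantom_breast_mask <- function(h, w, chest_wall = "left") {
  x <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  y <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  if (chest_wall == "right") x <- w - x
  a <- 0.97 * w            # semi-axis along the chest-wall -> nipple axis
  b <- 0.48 * h
  ellipse <- (x / a)^2 + ((y - h / 2) / b)^2 <= 1
  pectoral <- x / (0.32 * w) + y / (0.38 * h) < 1   # top chest-wall corner
  ellipse & !pectoral
}

#' Generate a synthetic mammogram phantom with ground truth
#'
#' Realizes a [phantom_spec()]: builds the breast mask, plants a dense-tissue
#' mask of exactly the target fraction of the breast area (to within one
#' pixel of rounding), and renders the 8-bit image as `adipose_level` on the
#' breast, `dense_level` on dense tissue and 0 off-breast, plus Gaussian
#' noise inside the mask, rounded and clipped to \[0, 255\].
#'
#' Dense tissue grows jointly out of `blob_count` disc seeds: every in-breast
#' pixel gets a scaled squared distance to its nearest blob centre
#' (distance^2 / radius^2, radii drawn uniformly so blobs differ in size) and
#' the planted mask is the target number of closest pixels — the nested
#' union of all discs grown together until the fraction is met. Under
#' `checkerboard` placement the candidate region is instead the alternating
#' half of the grid tiles, each filling from its own tile midpoint, which
#' plants a negative spatial autocorrelation; a `dense_fraction` exceeding
#' what those tiles can hold is rejected with the shortfall reported.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom`: `$image` (integer matrix), `$breast_mask`,
#'   `$true_dense_mask` (logical matrices), `$spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(dense_fraction = 0.25, seed = 7))
#' sum(ph$true_dense_mask) / sum(ph$breast_mask)   # ~0.25
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop("spec must be a phantom_spec", call. = FALSE)
  }
  h <- spec$image_height; w <- spec$image_width
  mask <- phantom_breast_mask(h, w, spec$chest_wall)
  grid <- make_grid(h, w)
  n_mask <- sum(mask)
  target <- round(spec$dense_fraction * n_mask)

  with_preserved_seed(spec$seed, {
    dense <- matrix(FALSE, h, w)
    if (target > 0) {
      idx <- tile_index_matrix(grid)
      if (spec$placement == "checkerboard") {
        tr <- (idx - 1L) %/% grid$cols
        tc <- (idx - 1L) %% grid$cols
        selected <- mask & ((tr + tc) %% 2L == 0L)
        cand <- which(selected)
        if (length(cand) < target) {
          stop(sprintf(paste0("dense_fraction %.3f unreachable under ",
                              "checkerboard placement: %d candidate pixels ",
                              "for a target of %d (shortfall %d)"),
                       spec$dense_fraction, length(cand), target,
                       target - length(cand)), call. = FALSE)
        }
        # fill each selected tile outward from its midpoint (pixel units)
        px <- (cand - 1L) %/% h + 0.5           # x = col - 0.5
        py <- (cand - 1L) %% h + 0.5
        mx <- grid$col_breaks[tc[cand] + 1L] +
          diff(grid$col_breaks)[tc[cand] + 1L] / 2
        my <- grid$row_breaks[tr[cand] + 1L] +
          diff(grid$row_breaks)[tr[cand] + 1L] / 2
        q <- (px - mx)^2 + (py - my)^2
      } else {
        zone_cols <- switch(spec$placement,
          uniform = seq_len(grid$cols),
          which(default_zones(spec$chest_wall)$zones == spec$placement))
        tc <- (idx - 1L) %% grid$cols + 1L
        centre_pool <- which(mask & matrix(tc %in% zone_cols, h, w))
        if (length(centre_pool) == 0L) {
          stop("no in-breast pixels available in the requested placement zone",
               call. = FALSE)
        }
        centres <- centre_pool[sample.int(length(centre_pool),
                                          spec$blob_count, replace = TRUE)]
        radii <- stats::runif(spec$blob_count, 0.06, 0.16) * min(h, w)
        cand <- which(mask)
        px <- (cand - 1L) %/% h + 0.5
        py <- (cand - 1L) %% h + 0.5
        cx <- (centres - 1L) %/% h + 0.5
        cy <- (centres - 1L) %% h + 0.5
        q <- rep(Inf, length(cand))
        for (b in seq_len(spec$blob_count)) {
          q <- pmin(q, ((px - cx[b])^2 + (py - cy[b])^2) / radii[b]^2)
        }
      }
      dense[cand[order(q)[seq_len(target)]]] <- TRUE
    }

    img <- matrix(0, h, w)
    img[mask] <- spec$adipose_level
    img[dense] <- spec$dense_level
    if (spec$noise_sd > 0) {
      img[mask] <- img[mask] + stats::rnorm(n_mask, 0, spec$noise_sd)
    }
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    structure(list(image = img, breast_mask = mask, true_dense_mask = dense,
                   spec = spec),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(paste0("phantom: %dx%d, %d breast px, planted dense fraction ",
                     "%.3f (target %.3f), placement %s, seed %d\n"),
              x$spec$image_height, x$spec$image_width, sum(x$breast_mask),
              sum(x$true_dense_mask) / sum(x$breast_mask),
              x$spec$dense_fraction, x$spec$placement, x$spec$seed))
  invisible(x)
}

#' Generate a synthetic screening cohort with planted effects
#'
#' Draws `n` subjects with ages uniform on 35-90 and a planted per-subject
#' dense fraction `base_fraction + age_slope * (age - mean age) + noise`
#' (clipped to \[0, 1\]), assigns BI-RADS-like density groups A-D by planted-
#' fraction quartiles, and renders one phantom per subject. Each group's
#' share of subjects with blob-clustered placement (vs. the scattered
#' checkerboard placement) follows `clustered_share_by_group`; the defaults
#' are the clustered-pattern proportions reported for screening BI-RADS
#' groups A-D (74.0, 66.1, 46.2, 49.2%). Clustered placements favour the
#' middle zone in mature subjects (< 65 years) and split between posterior
#' and middle in older subjects, so a middle-zone PD excess in the mature
#' group is planted alongside the negative age-density slope.
#'
#' @param n Number of subjects (>= 2).
#' @param age_slope Change in planted dense fraction per year of age
#'   (default -0.004, i.e. -0.4 PD percentage points per year).
#' @param clustered_share_by_group Named fractions for groups A-D.
#' @param seed Integer RNG seed for the whole cohort.
#' @param base_fraction Mean planted dense fraction at the mean age.
#' @param fraction_sd SD of the subject-level fraction noise.
#' @param image_height,image_width,noise_sd,blob_count Passed to each
#'   subject's [phantom_spec()] (desk-scale defaults).
#' @param mature_placement_probs,older_placement_probs Zone probabilities
#'   (posterior, middle, anterior) for clustered placements by age group.
#' @return A `phantom_cohort`: `$subjects` data frame (id, age, birads,
#'   planted_fraction, placement, seed) and `$phantoms` (list of
#'   [generate_phantom()] results in the same order).
#' @export
generate_cohort <- function(n, age_slope = -0.004,
                            clustered_share_by_group =
                              c(A = 0.740, B = 0.661, C = 0.462, D = 0.492),
                            seed = 1L,
                            base_fraction = 0.25, fraction_sd = 0.05,
                            image_height = 96L, image_width = 72L,
                            noise_sd = 10, blob_count = 4L,
                            mature_placement_probs =
                              c(posterior = 0.20, middle = 0.60,
                                anterior = 0.20),
                            older_placement_probs =
                              c(posterior = 0.45, middle = 0.45,
                                anterior = 0.10)) {
  if (n < 2) stop("a cohort needs at least 2 subjects", call. = FALSE)
  if (!all(c("A", "B", "C", "D") %in% names(clustered_share_by_group))) {
    clustered_share_by_group <-
      stats::setNames(rep_len(clustered_share_by_group, 4),
                      c("A", "B", "C", "D"))
  }
  with_preserved_seed(seed, {
    age <- round(stats::runif(n, 35, 90))
    frac <- base_fraction + age_slope * (age - mean(age)) +
      stats::rnorm(n, 0, fraction_sd)
    frac <- pmin(pmax(frac, 0), 1)
    qs <- stats::quantile(frac, c(0.25, 0.5, 0.75))
    birads <- cut(frac, breaks = c(-Inf, qs, Inf), labels = c("A", "B", "C", "D"))
    birads <- as.character(birads)
    clustered <- stats::runif(n) < clustered_share_by_group[birads]
    zones <- c("posterior", "middle", "anterior")
    placement <- character(n)
    for (i in seq_len(n)) {
      placement[i] <- if (!clustered[i]) "checkerboard" else {
        probs <- if (age[i] < 65) mature_placement_probs else
          older_placement_probs
        sample(zones, 1L, prob = probs)
      }
    }
    # checkerboard dense tissue can fill at most ~half the breast area
    # (alternating tiles); cap those subjects at a reachable fraction
    frac[placement == "checkerboard"] <-
      pmin(frac[placement == "checkerboard"], 0.45)
    subj_seed <- sample.int(.Machine$integer.max - 1L, n)
    phantoms <- vector("list", n)
    for (i in seq_len(n)) {
      phantoms[[i]] <- generate_phantom(phantom_spec(
        image_height = image_height, image_width = image_width,
        dense_fraction = frac[i], blob_count = blob_count,
        placement = placement[i], noise_sd = noise_sd,
        seed = subj_seed[i]))
    }
    structure(list(
      subjects = data.frame(id = sprintf("S%04d", seq_len(n)), age = age,
                            birads = birads, planted_fraction = frac,
                            placement = placement, seed = subj_seed,
                            stringsAsFactors = FALSE),
      phantoms = phantoms), class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d subjects (%s)\n", nrow(x$subjects),
              paste(sprintf("%s=%d", names(table(x$subjects$birads)),
                            table(x$subjects$birads)), collapse = ", ")))
  invisible(x)
}
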