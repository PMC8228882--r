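test_that("phantom spec validation rejects inconsistent parameters", {
  expect_error(phantom_spec(dense_fraction = 1.2), "dense_fraction")
  expect_error(phantom_spec(image_height = 40), "48x48")
  expect_error(phantom_spec(adipose_level = 200, dense_level = 150),
               "adipose_level")
  expect_error(phantom_spec(blob_count = 0), "blob_count")
})

test_that("zero dense fraction yields an empty ground-truth mask and PD 0", {
  ph <- small_phantom(dense_fraction = 0, seed = 3)
  expect_false(any(ph$true_dense_mask))
  expect_equal(overall_pd(ph$true_dense_mask, ph$breast_mask), 0)
})

test_that("identical spec and seed reproduce a bit-identical phantom", {
  a <- small_phantom(dense_fraction = 0.3, placement = "middle", seed = 11)
  b <- small_phantom(dense_fraction = 0.3, placement = "middle", seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(a$true_dense_mask, b$true_dense_mask)
  c <- small_phantom(dense_fraction = 0.3, placement = "middle", seed = 12)
  expect_false(identical(a$image, c$image))
})

test_that("planted dense fraction is recovered by independent pixel counting", {
  for (f in c(0.1, 0.25, 0.5)) {
    for (pl in c("uniform", "posterior", "checkerboard")) {
      ph <- small_phantom(dense_fraction = f, placement = pl, seed = 7)
      planted <- sum(ph$true_dense_mask) / sum(ph$breast_mask)
      # exact up to the one-pixel rounding of the target count
      expect_equal(sum(ph$true_dense_mask), round(f * sum(ph$breast_mask)))
      expect_lt(abs(planted - f), 0.02)
      expect_true(all(ph$breast_mask[ph$true_dense_mask]))   # dense inside breast
    }
  }
  ph <- generate_phantom(phantom_spec(dense_fraction = 0.25, seed = 7))
  frac <- sum(ph$true_dense_mask) / sum(ph$breast_mask)
  expect_gte(frac, 0.23)
  expect_lte(frac, 0.27)
})

test_that("off-mask pixels are exactly zero even with noise", {
  ph <- small_phantom(dense_fraction = 0.2, noise_sd = 15, seed = 5)
  expect_true(all(ph$image[!ph$breast_mask] == 0L))
  noiseless <- small_phantom(dense_fraction = 0.2, noise_sd = 0, seed = 5)
  expect_setequal(unique(as.vector(noiseless$image)), c(0L, 80L, 200L))
})

test_that("breast mask has MLO topology: chest-wall contact, pectoral corner cut", {
  ph <- small_phantom(seed = 1)
  m <- ph$breast_mask
  expect_true(any(m[, 1]))                 # touches the chest-wall edge
  expect_false(m[1, 1])                    # pectoral corner removed
  # pectoral triangle stays a modest share of the half-ellipse
  h <- nrow(m); w <- ncol(m)
  x <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  y <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  in_triangle <- x / (0.32 * w) + y / (0.38 * h) < 1
  expect_lt(sum(in_triangle) / (sum(m) + sum(in_triangle & !m)), 0.15)
})

test_that("unreachable checkerboard fraction is rejected with the shortfall", {
  expect_error(small_phantom(dense_fraction = 0.9,
                             placement = "checkerboard", seed = 2),
               "shortfall")
})

test_that("phantom generation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(small_phantom(seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("cohort generation validates n and reproduces under a seed", {
  expect_error(generate_cohort(1), "at least 2")
  a <- generate_cohort(6, seed = 21)
  b <- generate_cohort(6, seed = 21)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$phantoms[[3]]$image, b$phantoms[[3]]$image)
  expect_true(all(a$subjects$age >= 35 & a$subjects$age <= 90))
})

test_that("cohort plants the requested age-density slope and clustering", {
  co <- generate_cohort(200, age_slope = -0.004, seed = 13)
  expect_lt(cor(co$subjects$age, co$subjects$planted_fraction), 0)
  # zero slope: fractions vary only through subject noise, not age
  co0 <- generate_cohort(200, age_slope = 0, seed = 13)
  expect_gt(cor.test(co0$subjects$age, co0$subjects$planted_fraction)$p.value,
            0.01)
  # fully clustered groups get only zone placements
  co1 <- generate_cohort(60, clustered_share_by_group =
                           c(A = 1, B = 1, C = 1, D = 1), seed = 5)
  expect_true(all(co1$subjects$placement %in%
                    c("posterior", "middle", "anterior")))
  co2 <- generate_cohort(60, clustered_share_by_group =
                           c(A = 0, B = 0, C = 0, D = 0), seed = 5)
  expect_true(all(co2$subjects$placement == "checkerboard"))
})
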