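test_that("masked histogram counts in-mask pixels only", {
  img <- matrix(0L, 5, 5)
  img[1:2, 1:5] <- 7L
  mask <- matrix(FALSE, 5, 5)
  mask[1:2, 1:5] <- TRUE
  h <- masked_histogram(img, mask)
  expect_equal(h$counts[8], 10)
  expect_equal(sum(h$counts), 10)
  expect_equal(h$total, sum(mask))
  expect_error(masked_histogram(img, matrix(FALSE, 5, 5)), "empty mask")
})

test_that("noiseless two-level phantom has exactly two occupied bins", {
  ph <- small_phantom(dense_fraction = 0.3, noise_sd = 0, seed = 2)
  h <- masked_histogram(ph$image, ph$breast_mask)
  expect_equal(which(h$counts > 0) - 1L, c(80L, 200L))
  # frame scope adds the black background as a third bin
  hf <- masked_histogram(ph$image, scope = "frame")
  expect_equal(which(hf$counts > 0) - 1L, c(0L, 80L, 200L))
})

test_that("two-bin histograms give a flat entropy curve split at the low bin", {
  counts <- integer(256)
  counts[80 + 1] <- 700
  counts[200 + 1] <- 300
  expect_equal(kapur_threshold(counts), 80)
  expect_equal(oracle_kapur(counts), 80)
})

test_that("uniform histogram thresholds at the entropy-balancing level 127", {
  counts <- rep(10L, 256)
  expect_equal(kapur_threshold(counts), 127)
})

test_that("kapur threshold equals the exhaustive brute-force argmax", {
  set.seed(2024)
  for (rep in 1:100) {
    counts <- random_histogram()
    expect_identical(kapur_threshold(counts), oracle_kapur(counts))
  }
})

test_that("entropy argmax is invariant to uniform count scaling", {
  set.seed(7)
  for (rep in 1:20) {
    counts <- random_histogram()
    expect_identical(kapur_threshold(counts), kapur_threshold(counts * 13L))
  }
})

test_that("single-bin histograms cannot be split", {
  counts <- integer(256)
  counts[42] <- 100
  expect_error(kapur_threshold(counts), "two distinct")
})

test_that("segmentation thresholds strictly above t within the mask", {
  ph <- small_phantom(dense_fraction = 0.25, noise_sd = 0, seed = 4)
  empty <- segment(ph$image, ph$breast_mask, 254)
  expect_false(any(empty$pixels))
  all_in <- segment(ph$image, ph$breast_mask, 0)
  expect_equal(all_in$pixels, ph$breast_mask)
  # any threshold between the two tissue levels recovers the ground truth
  for (t in c(81, 140, 199)) {
    d <- segment(ph$image, ph$breast_mask, t)
    expect_identical(d$pixels, ph$true_dense_mask)
  }
  # ties at the threshold level fall in the non-dense class
  at_level <- segment(ph$image, ph$breast_mask, 200)
  expect_false(any(at_level$pixels))
  expect_equal(segment(ph$image, ph$breast_mask, 140)$threshold, 140L)
})

test_that("overall PD is the dense share of the breast area", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:20] <- TRUE
  dense <- matrix(FALSE, 20, 20)
  dense[1:5, 1:10] <- TRUE
  expect_equal(overall_pd(dense, mask), 25)
  expect_equal(overall_pd(mask, mask), 100)
  expect_equal(overall_pd(matrix(FALSE, 20, 20), mask), 0)
  expect_error(overall_pd(dense, matrix(FALSE, 20, 20)), "empty mask")
})

test_that("overall PD is monotone nonincreasing in the threshold", {
  ph <- small_phantom(dense_fraction = 0.3, noise_sd = 12, seed = 6)
  pds <- vapply(seq(0, 254, by = 2), function(t) {
    overall_pd(segment(ph$image, ph$breast_mask, t), ph$breast_mask)
  }, numeric(1))
  expect_true(all(diff(pds) <= 0))
})

test_that("the full segmentation path recovers planted density", {
  # noiseless: exact; noisy: within a few percentage points
  for (f in c(0.1, 0.4)) {
    ph <- small_phantom(dense_fraction = f, noise_sd = 0, seed = 8)
    q <- quantify_density(ph$image, ph$breast_mask)
    expect_equal(q$overall_pd,
                 100 * sum(ph$true_dense_mask) / sum(ph$breast_mask))
    phn <- small_phantom(dense_fraction = f, noise_sd = 10, seed = 8)
    qn <- quantify_density(phn$image, phn$breast_mask)
    expect_lt(abs(qn$overall_pd - 100 * f), 5)
  }
})
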