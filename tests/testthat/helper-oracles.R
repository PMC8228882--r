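# Independent brute-force oracles. Deliberately written as plain loops over
# the textbook definitions so they share no code path with the package.

# Two-class maximum-entropy threshold by exhaustive search over all 255
# candidate splits, entropies accumulated bin by bin.
oracle_kapur <- function(counts) {
  total <- sum(counts)
  best_t <- NA_integer_
  best_psi <- -Inf
  for (t in 0:254) {
    n_low <- sum(counts[1:(t + 1)])
    if (n_low == 0 || n_low == total) next
    h_low <- 0
    for (i in 0:t) {
      p <- counts[i + 1] / total
      if (p > 0) {
        q <- p / (n_low / total)
        h_low <- h_low - q * log(q)
      }
    }
    h_high <- 0
    for (i in (t + 1):255) {
      p <- counts[i + 1] / total
      if (p > 0) {
        q <- p / (1 - n_low / total)
        h_high <- h_high - q * log(q)
      }
    }
    psi <- h_low + h_high
    if (psi > best_psi) {       # strict: keeps the smallest maximizer
      best_psi <- psi
      best_t <- t
    }
  }
  best_t
}

# Moran's I by explicit double loops over ordered tile pairs.
oracle_moran <- function(values, W) {
  n <- length(values)
  xbar <- mean(values)
  s0 <- 0
  cross <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      s0 <- s0 + W[i, j]
      cross <- cross + W[i, j] * (values[i] - xbar) * (values[j] - xbar)
    }
  }
  (n / s0) * cross / sum((values - xbar)^2)
}

# Random sparse-ish 256-bin histogram with at least two occupied bins.
random_histogram <- function() {
  k <- sample(2:40, 1)
  levels <- sample(0:255, k)
  counts <- integer(256)
  counts[levels + 1] <- sample(1:500, k, replace = TRUE)
  counts
}

small_phantom <- function(...) {
  generate_phantom(phantom_spec(image_height = 96, image_width = 72, ...))
}
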