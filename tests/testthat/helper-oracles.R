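# Independent oracles used across the suite. Each re-derives the quantity
# by the most direct (naive) route so the fast implementations are checked
# against something they do not share code with.

# Naive Huang minimum-fuzziness threshold: explicit loop over candidate
# bin edges, recomputing side means and entropies from scratch.
huang_oracle <- function(values, bins = 256L) {
  v <- as.numeric(values)
  rng <- range(v)
  width <- diff(rng) / bins
  bin_of <- pmin(bins, 1L + floor((v - rng[1]) / diff(rng) * bins))
  h <- tabulate(bin_of, bins)
  centers <- rng[1] + (seq_len(bins) - 0.5) * width
  nz <- which(h > 0)
  C <- centers[nz[length(nz)]] - centers[nz[1]]
  ent_of <- function(u) if (u <= 0 || u >= 1) 0 else -u * log(u) - (1 - u) * log(1 - u)
  best_t <- NA; best_e <- Inf
  for (t in nz[1]:(nz[length(nz)] - 1L)) {
    lo <- 1:t; hi <- (t + 1L):bins
    m0 <- sum(h[lo] * centers[lo]) / sum(h[lo])
    m1 <- sum(h[hi] * centers[hi]) / sum(h[hi])
    e <- 0
    for (g in lo) if (h[g] > 0)
      e <- e + h[g] * ent_of(1 / (1 + abs(centers[g] - m0) / C))
    for (g in hi) if (h[g] > 0)
      e <- e + h[g] * ent_of(1 / (1 + abs(centers[g] - m1) / C))
    if (e < best_e - 1e-12) { best_e <- e; best_t <- t }
  }
  rng[1] + best_t * width
}

# Brute-force exact two-tailed Mann-Whitney p by enumerating every group
# assignment of the pooled values directly (no rank pre-computation reuse).
mw_oracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  n <- length(pool)
  u_of <- function(a, b) {
    # direct pair counting with half credit for ties
    sum(outer(a, b, ">") + 0.5 * outer(a, b, "=="))
  }
  U <- u_of(x, y)
  ucrit <- min(U, n1 * (n - n1) - U)
  sets <- utils::combn(n, n1)
  hits <- 0
  for (k in seq_len(ncol(sets))) {
    a <- pool[sets[, k]]; b <- pool[-sets[, k]]
    if (u_of(a, b) <= ucrit + 1e-9) hits <- hits + 1
  }
  min(1, 2 * hits / ncol(sets))
}

# Naive box-mean filter with symmetric (mirror, edge-included) padding.
mean_filter_oracle <- function(m, k) {
  pad <- (k - 1) %/% 2
  ri <- c(pad:1, 1:nrow(m), nrow(m):(nrow(m) - pad + 1))
  ci <- c(pad:1, 1:ncol(m), ncol(m):(ncol(m) - pad + 1))
  p <- m[ri, ci]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    out[i, j] <- mean(p[i:(i + 2 * pad), j:(j + 2 * pad)])
  out
}

# Per-pixel point-in-polygon by explicit ray casting, one pixel at a time.
polygon_oracle <- function(vertices, image_shape_px, pixel_size_um) {
  nr <- image_shape_px[1]; nc <- image_shape_px[2]
  out <- matrix(FALSE, nr, nc)
  v <- rbind(vertices, vertices[1, ])
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    px <- (j - 0.5) * pixel_size_um; py <- (i - 0.5) * pixel_size_um
    crossings <- 0
    for (e in seq_len(nrow(v) - 1)) {
      x1 <- v[e, 1]; y1 <- v[e, 2]; x2 <- v[e + 1, 1]; y2 <- v[e + 1, 2]
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < xint) crossings <- crossings + 1
      }
    }
    out[i, j] <- crossings %% 2 == 1
  }
  out
}

# Random histogram-like sample for threshold tests: a lumpy mixture.
random_histogram_sample <- function(n = 2000) {
  k <- sample(2:4, 1)
  unlist(lapply(seq_len(k), function(i)
    rnorm(ceiling(n / k), mean = runif(1, 0, 10), sd = runif(1, 0.1, 2))))
}

# Match planted particles to detected centroids within radius + slack um.
match_particles <- function(truth, detected, slack_um = 4) {
  if (nrow(truth) == 0) return(logical(0))
  vapply(seq_len(nrow(truth)), function(i) {
    d <- sqrt((detected$x_um - truth$x_um[i])^2 +
                (detected$y_um - truth$y_um[i])^2)
    any(d < truth$radius_um[i] + slack_um)
  }, logical(1))
}
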