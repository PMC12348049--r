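test_that("a delta-function decay maps to the (1, 0) phasor limit", {
  counts <- array(0, c(1, 1, 256))
  counts[1, 1, 1] <- 1e5
  st <- decay_stack(counts, 12500 / 256)
  ph <- phasor_transform(st)
  expect_equal(ph$G[1, 1], 1, tolerance = 0.01)
  expect_equal(ph$S[1, 1], 0, tolerance = 0.02)
})

test_that("omega tau = 1 lands at the continuous closed form (0.5, 0.5)", {
  window <- 1e5; n_bins <- 4096
  tau <- window / (2 * pi)
  p <- lipoquant:::discretized_exponential(tau, window / n_bins, n_bins)
  st <- decay_stack(array(1e7 * p, c(1, 1, n_bins)), window / n_bins)
  ph <- phasor_transform(st)
  expect_equal(ph$G[1, 1], 0.5, tolerance = 0.01)
  expect_equal(ph$S[1, 1], 0.5, tolerance = 0.01)
})

test_that("monoexponential phasors lie on the universal semicircle", {
  for (tau in c(200, 400, 1000, 3000)) {
    pp <- phasor_point(tau, 12500, 256)
    expect_lt(abs((pp["G"] - 0.5)^2 + pp["S"]^2 - 0.25), 5e-3)
  }
})

test_that("empirical phasors match the discretized closed form within noise", {
  spec <- decay_sim_spec(lifetimes_ps = 400,
                         class_fractions = list(lipofuscin = 1),
                         photons_per_pixel = 1e5, seed = 41)
  st <- generate_decay_stack(spec, matrix(1L, 5, 5))
  ph <- phasor_transform(st)
  pp <- phasor_point(400, spec$window_ps, spec$n_bins)
  # 3 sigma with sigma ~ 1/sqrt(2 N) per coordinate
  tol <- 3 / sqrt(2 * 1e5)
  expect_true(all(abs(ph$G - pp["G"]) < 3 * tol))
  expect_true(all(abs(ph$S - pp["S"]) < 3 * tol))
})

test_that("the phasor of a mixture is the count-weighted combination", {
  n_bins <- 256; bw <- 12500 / 256
  p1 <- lipoquant:::discretized_exponential(400, bw, n_bins)
  p2 <- lipoquant:::discretized_exponential(2000, bw, n_bins)
  w <- 0.3
  mix <- 1e6 * (w * p1 + (1 - w) * p2)
  stm <- decay_stack(array(mix, c(1, 1, n_bins)), bw)
  phm <- phasor_transform(stm)
  g1 <- phasor_point(400, 12500, n_bins); g2 <- phasor_point(2000, 12500, n_bins)
  expect_equal(phm$G[1, 1], w * g1[["G"]] + (1 - w) * g2[["G"]], tolerance = 1e-9)
  expect_equal(phm$S[1, 1], w * g1[["S"]] + (1 - w) * g2[["S"]], tolerance = 1e-9)
})

test_that("zero-count pixels are flagged invalid and excluded from clusters", {
  counts <- array(0, c(2, 2, 64))
  counts[1, 1, ] <- 10
  st <- decay_stack(counts, 50)
  ph <- phasor_transform(st)
  expect_true(is.na(ph$G[2, 2]))
  big <- phasor_ellipse(0.5, 0.25, 10, 10)
  m <- select_cluster(ph, big)
  expect_identical(m$mask, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
})

test_that("an all-covering ellipse selects every valid pixel and a degenerate one none", {
  spec <- decay_sim_spec(photons_per_pixel = 500, seed = 6)
  st <- generate_decay_stack(spec, matrix(1L, 4, 4))
  ph <- phasor_transform(st)
  all_m <- select_cluster(ph, phasor_ellipse(0.5, 0.25, 10, 10))
  expect_true(all(all_m$mask))
  none <- select_cluster(ph, phasor_ellipse(-5, -5, 1e-6, 1e-6))
  expect_false(any(none$mask))
})

test_that("phasor cluster selection recovers the short-lifetime class", {
  spec <- decay_sim_spec(lifetimes_ps = c(400, 2000),
                         class_fractions = list(lipo = c(1, 0), bg = c(0, 1)),
                         photons_per_pixel = 2000, seed = 19)
  cm <- matrix(2L, 24, 24)
  cm[5:12, 5:20] <- 1L
  st <- generate_decay_stack(spec, cm)
  ph <- phasor_transform(st)
  pp <- phasor_point(400, spec$window_ps, spec$n_bins)
  m <- select_cluster(ph, phasor_ellipse(pp[["G"]], pp[["S"]], 0.05, 0.05))
  d <- dice(m$mask, cm == 1L)
  expect_gte(d$dice, 0.9)
})

test_that("pooling sums histograms and scales with mask size", {
  counts <- array(rep(1:16, each = 9), c(3, 3, 16))
  st <- decay_stack(counts, 100)
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  expect_equal(pool_decay(st, one), as.numeric(1:16))
  expect_equal(pool_decay(st, matrix(TRUE, 3, 3)), 9 * as.numeric(1:16))
  expect_error(pool_decay(st, matrix(FALSE, 3, 3)), "no pixels")
})

test_that("ML fit is exact on a noise-free discretized monoexponential", {
  h <- 1e6 * lipoquant:::discretized_exponential(400, 12500 / 256, 256)
  fit <- fit_decay_ml(h, 1, 12500 / 256)
  expect_lt(abs(fit$tau_ps - 400), 1)
})

test_that("two-component ML fit recovers both lifetimes within 15%", {
  spec <- decay_sim_spec(lifetimes_ps = c(400, 2000),
                         class_fractions = list(mix = c(0.5, 0.5)),
                         photons_per_pixel = 1e5, seed = 23)
  st <- generate_decay_stack(spec, matrix(1L, 1, 1))
  fit <- fit_decay_ml(as.numeric(st$counts[1, 1, ]), 2, spec$bin_width_ps)
  expect_lt(abs(fit$tau_ps[1] - 400) / 400, 0.15)
  expect_lt(abs(fit$tau_ps[2] - 2000) / 2000, 0.15)
  expect_equal(sum(fit$alpha), 1, tolerance = 1e-9)
})

test_that("low-count histograms warn and empty histograms error", {
  h <- c(rep(3, 10), rep(0, 54))
  expect_warning(fit_decay_ml(h, 1, 100), "unreliable")
  expect_error(fit_decay_ml(rep(0, 64), 1, 100), "empty")
})

test_that("lifetime image is flat at the true lifetime and NA where empty", {
  spec <- decay_sim_spec(lifetimes_ps = 400,
                         class_fractions = list(lipo = 1),
                         photons_per_pixel = 5e3, seed = 29)
  cm <- matrix(1L, 4, 4); cm[1, 1] <- 0L
  st <- generate_decay_stack(spec, cm)
  li <- lifetime_image(st, min_counts = 100)
  expect_true(is.na(li[1, 1]))
  expect_lt(max(abs(li[-1] - 400)), 40)
})

test_that("ellipse refinement homes in on the target-lifetime cluster", {
  spec <- decay_sim_spec(lifetimes_ps = c(400, 2000),
                         class_fractions = list(lipo = c(1, 0), bg = c(0, 1)),
                         photons_per_pixel = 2000, seed = 37)
  cm <- matrix(2L, 12, 12); cm[4:9, 4:9] <- 1L
  st <- generate_decay_stack(spec, cm)
  ph <- phasor_transform(st)
  pp <- phasor_point(430, spec$window_ps, spec$n_bins)  # slightly off centre
  ref <- refine_phasor_ellipse(ph, st,
                               phasor_ellipse(pp[["G"]], pp[["S"]], 0.03, 0.03))
  expect_lt(abs(ref$fit$tau_mean_ps - 400), 40)
})
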