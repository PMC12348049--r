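test_that("zero particle density yields an empty ground truth", {
  g <- generate_granule_image(granule_field_spec(
    image_shape_px = c(64, 64), particle_density_per_mm2 = 0, seed = 1))
  expect_equal(nrow(g$truth$particles), 0)
  expect_false(any(g$truth$mask$mask))
  expect_true(all(g$image$pixels > 0))
})

test_that("fixed-count mode plants exactly density times area particles", {
  # 400 px at 2.5 um/px = 1 mm on each side, so exactly 1 mm^2
  g <- generate_granule_image(granule_field_spec(
    image_shape_px = c(400, 400), pixel_size_um = 2.5,
    particle_density_per_mm2 = 500, count_mode = "fixed", seed = 5))
  expect_equal(nrow(g$truth$particles), 500)
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- granule_field_spec(image_shape_px = c(80, 80),
                             particle_density_per_mm2 = 400, seed = 123)
  g1 <- generate_granule_image(spec)
  g2 <- generate_granule_image(spec)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(g1$truth$particles, g2$truth$particles)
})

test_that("poisson-count planting is unbiased over replicates", {
  set.seed(77)
  spec <- granule_field_spec(image_shape_px = c(64, 64),
                             particle_density_per_mm2 = 2000,
                             count_mode = "poisson", seed = NULL)
  area_mm2 <- (64 * 3 / 1000)^2
  counts <- replicate(100, nrow(generate_granule_image(spec)$truth$particles))
  expected <- 2000 * area_mm2
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / 100))
})

test_that("ground-truth mask equals the union of half-maximum discs", {
  g <- generate_granule_image(granule_field_spec(
    image_shape_px = c(100, 100), particle_density_per_mm2 = 150, seed = 8))
  p <- g$truth$particles
  px <- g$image$pixel_size_um
  manual <- matrix(FALSE, 100, 100)
  xs <- (seq_len(100) - 0.5) * px
  for (i in seq_len(nrow(p))) {
    d2 <- outer((xs - p$y_um[i])^2, (xs - p$x_um[i])^2, "+")
    manual <- manual | (d2 <= p$radius_um[i]^2)
  }
  expect_identical(g$truth$mask$mask, manual)
})

test_that("overfull fields (majority particle) are rejected", {
  expect_error(generate_granule_image(granule_field_spec(
    image_shape_px = c(32, 32), particle_density_per_mm2 = 5e4,
    radius_mean_um = 3, seed = 1)), ">50%")
})

test_that("an all-zero photon budget gives all-zero histograms", {
  spec <- decay_sim_spec(photons_per_pixel = 0, seed = 2)
  st <- generate_decay_stack(spec, matrix(1L, 4, 4))
  expect_true(all(st$counts == 0))
})

test_that("simulated mean arrival time matches the truncated-exponential value", {
  spec <- decay_sim_spec(lifetimes_ps = 400,
                         class_fractions = list(lipofuscin = 1),
                         bin_width_ps = 25, n_bins = 256,
                         photons_per_pixel = 1e4, seed = 31)
  st <- generate_decay_stack(spec, matrix(1L, 10, 10))
  pooled <- pool_decay(st, matrix(TRUE, 10, 10))
  tk <- (seq_len(256) - 0.5) * 25
  p <- lipoquant:::discretized_exponential(400, 25, 256)
  analytic_mean <- sum(p * tk)
  analytic_sd <- sqrt(sum(p * tk^2) - analytic_mean^2)
  emp_mean <- sum(pooled * tk) / sum(pooled)
  expect_lt(abs(emp_mean - analytic_mean), 3 * analytic_sd / sqrt(sum(pooled)))
  expect_lt(abs(analytic_mean - 400), 15)  # truncation+binning bias is small
})

test_that("pooled decay histogram passes goodness of fit against the model", {
  spec <- decay_sim_spec(lifetimes_ps = 400,
                         class_fractions = list(lipofuscin = 1),
                         photons_per_pixel = 1e4, seed = 13)
  st <- generate_decay_stack(spec, matrix(1L, 10, 10))
  pooled <- pool_decay(st, matrix(TRUE, 10, 10))
  p <- lipoquant:::discretized_exponential(400, spec$bin_width_ps, spec$n_bins)
  gof <- suppressWarnings(stats::chisq.test(pooled, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("two decay classes are distinguishable by fitted lifetime", {
  spec <- decay_sim_spec(lifetimes_ps = c(400, 2000),
                         class_fractions = list(lipo = c(1, 0),
                                                bg = c(0, 1)),
                         photons_per_pixel = 5e3, seed = 17)
  cm <- matrix(rep(c(1L, 2L), each = 32), 8, 8)
  st <- generate_decay_stack(spec, cm)
  f1 <- fit_decay_ml(pool_decay(st, cm == 1L), 1, spec$bin_width_ps)
  f2 <- fit_decay_ml(pool_decay(st, cm == 2L), 1, spec$bin_width_ps)
  expect_lt(abs(f1$tau_ps - 400), 40)
  expect_lt(abs(f2$tau_ps - 2000), 200)
})

test_that("short measurement windows trigger a truncation warning", {
  expect_warning(decay_sim_spec(lifetimes_ps = c(400, 6000)), "truncation")
})

test_that("noise-free A-scans recover the scattering coefficient exactly", {
  vol <- generate_scattering_volume(gm_mus = 8, wm_mus = 12,
                                    shape = c(4, 4, 30), noise_sd = 0)
  fit <- fit_scattering(vol)
  expect_equal(fit$mus[vol$masks$GM], rep(8, sum(vol$masks$GM)),
               tolerance = 1e-9)
  expect_equal(fit$mus[vol$masks$WM], rep(12, sum(vol$masks$WM)),
               tolerance = 1e-9)
})

test_that("degenerate scattering volumes are rejected", {
  expect_error(generate_scattering_volume(shape = c(4, 4, 0)), "depth")
  expect_error(generate_scattering_volume(gm_mus = 10, wm_mus = 5), "exceed")
})

test_that("cohort effects may only target the sulcus", {
  expect_error(cohort_spec(effects = data.frame(
    group = "AD", side = "crest", tissue = "GM_supra",
    density_mult = 2, radius_mult = 1)), "crest")
})

test_that("cohort expectations are nonnegative and crest is unchanged", {
  co <- generate_cohort(cohort_spec(seed = 4), render = FALSE)
  e <- co$expectations
  expect_true(all(e$density_per_mm2 >= 0))
  expect_true(all(e$area_fraction_pct >= 0))
  # per subject, crest expectations carry no group effect: the AD/NC crest
  # group means differ only through age and subject scale, not multipliers
  base_rad <- tapply(e$mean_radius_um[e$side == "crest"],
                     e$tissue[e$side == "crest"], unique)
  expect_true(all(lengths(base_rad) == 1))
})

test_that("a null cohort yields group-mean SOCR near one", {
  set.seed(55)
  null_effects <- data.frame(group = character(), side = character(),
                             tissue = character(), density_mult = numeric(),
                             radius_mult = numeric())
  ratios <- replicate(30, {
    co <- generate_cohort(cohort_spec(effects = null_effects, seed = NULL),
                          tissues = "GM_supra", render = FALSE)
    st <- socr(analyze_cohort(co))
    mean(st$socr[st$metric == "number_density_per_mm2"])
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("intensity and decay TIFF round trips preserve data", {
  g <- generate_granule_image(granule_field_spec(
    image_shape_px = c(32, 32), particle_density_per_mm2 = 500, seed = 2))
  f <- tempfile(fileext = ".tif")
  write_intensity_tiff(g$image, f)
  back <- read_intensity_tiff(f)
  expect_equal(back$pixel_size_um, 3)
  expect_equal(back$pixels, g$image$pixels, tolerance = 1e-3)

  st <- generate_decay_stack(decay_sim_spec(photons_per_pixel = 200, seed = 3),
                             matrix(1L, 4, 4))
  f2 <- tempfile(fileext = ".tif")
  write_decay_tiff(st, f2)
  back2 <- read_decay_tiff(f2)
  expect_equal(back2$counts, st$counts, tolerance = 0)
  expect_equal(back2$bin_width_ps, st$bin_width_ps)
})
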