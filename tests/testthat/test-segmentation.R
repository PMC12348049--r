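test_that("background normalization maps a constant image to all ones", {
  img <- intensity_image(matrix(7.5, 40, 40), 3)
  norm <- normalize_background(img, 30)
  expect_equal(norm$pixels, matrix(1, 40, 40))
})

test_that("normalization flattens a smooth ramp to near unity away from borders", {
  ramp <- outer(seq(1, 2, length.out = 60), rep(1, 60))
  norm <- normalize_background(intensity_image(ramp, 3), 50)
  interior <- norm$pixels[10:51, 10:51]
  expect_true(all(interior > 0.9 & interior < 1.1))
})

test_that("single bright pixel ratio matches direct arithmetic", {
  m <- matrix(1, 41, 41)
  m[21, 21] <- 100
  norm <- normalize_background(intensity_image(m, 3), 51)  # 17 px kernel
  expect_equal(norm$pixels[21, 21], 100 / ((99 + 17^2) / 17^2),
               tolerance = 1e-12)
})

test_that("mean filter equals the brute-force mirror-padded oracle", {
  set.seed(4)
  m <- matrix(runif(30 * 25), 30, 25)
  for (k in c(3, 7, 11))
    expect_equal(lipoquant:::mean_filter(m, k), mean_filter_oracle(m, k),
                 tolerance = 1e-10)
})

test_that("normalization rejects kernels larger than the image", {
  img <- intensity_image(matrix(1, 10, 10), 3)
  expect_error(normalize_background(img, 100), "larger than the image")
})

test_that("huang threshold splits a symmetric two-spike histogram", {
  v <- c(rep(0, 100), rep(255, 100))
  thr <- huang_threshold(v, 256)
  expect_gt(thr, 0)
  expect_lt(thr, 255)
})

test_that("huang threshold errors on constant input", {
  expect_error(huang_threshold(rep(3, 50)), "constant")
})

test_that("huang threshold equals the exhaustive-search oracle", {
  set.seed(11)
  for (i in 1:200) {
    v <- random_histogram_sample(500)
    expect_equal(huang_threshold(v, 64), huang_oracle(v, 64),
                 tolerance = 1e-10)
  }
})

test_that("huang threshold of a normalized granule field lies between 1 and the contrast", {
  g <- generate_granule_image(granule_field_spec(
    image_shape_px = c(200, 200), particle_density_per_mm2 = 800,
    particle_contrast = 2, seed = 21))
  norm <- normalize_background(g$image, 50)
  thr <- huang_threshold(norm$pixels, 256)
  expect_gt(thr, 0.9)
  expect_lt(thr, 2)
})

test_that("a flat particle-free field segments to an empty table", {
  img <- intensity_image(matrix(5, 64, 64), 3)
  seg <- segment_lipofuscin(img)
  expect_equal(nrow(seg$particles), 0)
  expect_false(any(seg$mask$mask))
})

test_that("planted particles are recovered with high recall and precision", {
  g <- generate_granule_image(granule_field_spec(
    image_shape_px = c(334, 334), particle_density_per_mm2 = 100,
    radius_mean_um = 2.5, radius_sd_um = 0.5,  # resolvable at 3 um pixels
    particle_contrast = 2, seed = 7))
  seg <- segment_lipofuscin(g$image)
  hit <- match_particles(g$truth$particles, seg$particles)
  expect_gte(mean(hit), 0.95)
  matched <- vapply(seq_len(nrow(seg$particles)), function(i) {
    d <- sqrt((g$truth$particles$x_um - seg$particles$x_um[i])^2 +
                (g$truth$particles$y_um - seg$particles$y_um[i])^2)
    any(d < g$truth$particles$radius_um + 4)
  }, logical(1))
  expect_gte(mean(matched), 0.9)
})

test_that("a 25-pixel component reports the closed-form equivalent radius", {
  m <- matrix(1, 64, 64)
  m[30:34, 30:34] <- 3
  seg <- segment_lipofuscin(intensity_image(m, 3))
  expect_equal(nrow(seg$particles), 1)
  expect_equal(seg$particles$area_px, 25)
  expect_equal(seg$particles$equivalent_radius_um, sqrt(225 / pi),
               tolerance = 1e-10)
})

test_that("segmentation is invariant to global intensity scaling", {
  g <- generate_granule_image(granule_field_spec(
    image_shape_px = c(150, 150), particle_density_per_mm2 = 300, seed = 3))
  s1 <- segment_lipofuscin(g$image)
  s2 <- segment_lipofuscin(intensity_image(g$image$pixels * 37.5, 3))
  expect_identical(s1$mask$mask, s2$mask$mask)
})

test_that("raising the lower bound never adds mask pixels and the clamp holds", {
  g <- generate_granule_image(granule_field_spec(
    image_shape_px = c(150, 150), particle_density_per_mm2 = 500, seed = 9))
  s1 <- segment_lipofuscin(g$image, segmentation_params(lower_bound = 1.15))
  s2 <- segment_lipofuscin(g$image, segmentation_params(lower_bound = 1.4))
  expect_true(all(s1$mask$mask | !s2$mask$mask))  # s2 subset of s1
  expect_gte(s1$threshold, 1.15)
  expect_gte(s2$threshold, 1.4)
})

test_that("8-connectivity joins diagonal pixels that 4-connectivity separates", {
  m <- matrix(1, 20, 20)
  m[5, 5] <- 5; m[6, 6] <- 5
  img <- intensity_image(m, 3)
  s8 <- segment_lipofuscin(img, segmentation_params(kernel_um = 30, connectivity = 8))
  s4 <- segment_lipofuscin(img, segmentation_params(kernel_um = 30, connectivity = 4))
  expect_equal(nrow(s8$particles), 1)
  expect_equal(nrow(s4$particles), 2)
})

test_that("min_area_px removes small components from mask and table", {
  set.seed(90)
  m <- matrix(1, 40, 40) * (1 + matrix(rnorm(1600, 0, 0.02), 40, 40))
  m[10, 10] <- 5                 # 1 px
  m[25:27, 25:27] <- 5           # 9 px
  img <- intensity_image(m, 3)
  seg <- segment_lipofuscin(img, segmentation_params(kernel_um = 30, min_area_px = 4))
  expect_equal(nrow(seg$particles), 1)
  expect_equal(sum(seg$mask$mask), 9)
})
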