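#' Dice coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Masks on different pixel grids are
#' first brought to the finer grid by nearest-neighbour replication (the
#' pixel pitches must be integer multiples). Two empty masks give a
#' flagged (NA) score, never 0 or 1.
#'
#' @param a,b [binary_mask()] objects (or logical matrices, assumed to
#'   share a grid).
#' @return class `dice_result`: `dice`, `n_a`, `n_b`, `n_intersect`,
#'   `flagged`.
#' @export
dice <- function(a, b) {
  pa <- if (inherits(a, "binary_mask")) a$pixel_size_um else 1
  pb <- if (inherits(b, "binary_mask")) b$pixel_size_um else 1
  ma <- if (inherits(a, "binary_mask")) a$mask else as.matrix(a)
  mb <- if (inherits(b, "binary_mask")) b$mask else as.matrix(b)
  if (pa != pb) {
    f <- max(pa, pb) / min(pa, pb)
    if (abs(f - round(f)) > 1e-6)
      stop("pixel sizes must be integer multiples for resampling", call. = FALSE)
    f <- as.integer(round(f))
    if (pa > pb) ma <- nn_upsample(ma, f) else mb <- nn_upsample(mb, f)
  }
  nr <- min(nrow(ma), nrow(mb)); nc <- min(ncol(ma), ncol(mb))
  ma <- ma[seq_len(nr), seq_len(nc)]; mb <- mb[seq_len(nr), seq_len(nc)]
  n_a <- sum(ma); n_b <- sum(mb); n_i <- sum(ma & mb)
  flagged <- (n_a + n_b) == 0
  structure(list(dice = if (flagged) NA_real_ else 2 * n_i / (n_a + n_b),
                 n_a = n_a, n_b = n_b, n_intersect = n_i, flagged = flagged),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  if (x$flagged) cat("dice_result: undefined (both masks empty)\n")
  else cat(sprintf("dice_result: %.4f (|A| = %d, |B| = %d, |A&B| = %d)\n",
                   x$dice, x$n_a, x$n_b, x$n_intersect))
  invisible(x)
}

#' Translation-only image alignment by cross-correlation
#'
#' Exhaustive search over integer pixel shifts within `max_shift_px`,
#' maximizing the normalized cross-correlation of the overlapping region.
#' Returns the shift (dy, dx) to apply to `b` so it best matches `a`.
#'
#' @param a,b [intensity_image()] objects or matrices on a common grid.
#' @param max_shift_px maximum absolute shift searched per axis.
#' @return integer vector c(dy, dx) and the achieved correlation as
#'   attribute "ncc".
#' @export
align_translation <- function(a, b, max_shift_px = 10L) {
  ma <- if (inherits(a, "intensity_image")) a$pixels else as.matrix(a)
  mb <- if (inherits(b, "intensity_image")) b$pixels else as.matrix(b)
  best <- c(0L, 0L); best_ncc <- -Inf
  for (dy in -max_shift_px:max_shift_px) for (dx in -max_shift_px:max_shift_px) {
    ra <- max(1, 1 + dy):min(nrow(ma), nrow(mb) + dy)
    ca <- max(1, 1 + dx):min(ncol(ma), ncol(mb) + dx)
    if (length(ra) < 4 || length(ca) < 4) next
    pa <- ma[ra, ca]; pb <- mb[ra - dy, ca - dx]
    sa <- stats::sd(pa); sb <- stats::sd(pb)
    if (sa == 0 || sb == 0) next
    ncc <- mean((pa - mean(pa)) * (pb - mean(pb))) / (sa * sb)
    if (ncc > best_ncc) { best_ncc <- ncc; best <- c(dy, dx) }
  }
  structure(as.integer(best), ncc = best_ncc)
}

# Apply an integer (dy, dx) shift to a logical matrix, zero filling.
shift_mask <- function(m, dy, dx) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
  cs <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
  out[rs, cs] <- m[rs - dy, cs - dx]
  out
}

#' Resolution-mismatch benchmark specification
#'
#' Describes the validation experiment in which a high-resolution (FLIM
#' grade, 0.5 um) field supplies the ground truth and the segmentation is
#' run on the same field box-averaged to the integrated-system pitch
#' (3 um). The particle population mixes resolvable granules with a
#' sub-resolution fraction that the coarse arm cannot recover.
#'
#' @param hi_res_pixel_um ground-truth pixel pitch (default 0.5).
#' @param lo_res_pixel_um segmentation pixel pitch (default 3); must be an
#'   integer multiple of the fine pitch.
#' @param field_um square field side, um (default 1000).
#' @param particle_density_per_mm2 total particle density.
#' @param subres_fraction fraction of particles drawn from the small
#'   (sub-resolution) size component.
#' @param radius_main_um,radius_main_sd_um resolvable size component (um).
#' @param radius_sub_um,radius_sub_sd_um sub-resolution component (um).
#' @param particle_contrast peak/background ratio.
#' @param use_flim_truth when TRUE the ground truth is a phasor-cluster
#'   segmentation of a simulated high-resolution decay stack; when FALSE
#'   (default) the planted half-maximum mask is used directly.
#' @param seg_params [segmentation_params()] for the coarse arm.
#' @param seed integer seed or NULL.
#' @return class `resolution_bench_spec`.
#' @export
resolution_bench_spec <- function(hi_res_pixel_um = 0.5,
                                  lo_res_pixel_um = 3,
                                  field_um = 1000,
                                  particle_density_per_mm2 = 400,
                                  subres_fraction = 0.35,
                                  radius_main_um = 2.5,
                                  radius_main_sd_um = 0.7,
                                  radius_sub_um = 0.8,
                                  radius_sub_sd_um = 0.25,
                                  particle_contrast = 1.5,
                                  use_flim_truth = FALSE,
                                  seg_params = segmentation_params(),
                                  seed = NULL) {
  if (hi_res_pixel_um > lo_res_pixel_um)
    stop("hi_res_pixel_um must not be coarser than lo_res_pixel_um",
         call. = FALSE)
  f <- lo_res_pixel_um / hi_res_pixel_um
  if (abs(f - round(f)) > 1e-6)
    stop("lo_res pitch must be an integer multiple of hi_res pitch", call. = FALSE)
  structure(list(hi_res_pixel_um = hi_res_pixel_um,
                 lo_res_pixel_um = lo_res_pixel_um, field_um = field_um,
                 particle_density_per_mm2 = particle_density_per_mm2,
                 subres_fraction = subres_fraction,
                 radius_main_um = radius_main_um,
                 radius_main_sd_um = radius_main_sd_um,
                 radius_sub_um = radius_sub_um,
                 radius_sub_sd_um = radius_sub_sd_um,
                 particle_contrast = particle_contrast,
                 use_flim_truth = use_flim_truth,
                 seg_params = seg_params, seed = seed),
            class = "resolution_bench_spec")
}

#' Run the resolution-mismatch validation benchmark
#'
#' Simulates the high-resolution granule field, forms the ground-truth mask
#' (planted half-maximum discs, or a phasor-cluster segmentation of a
#' simulated decay stack when `use_flim_truth`), box-averages the intensity
#' to the coarse pitch, segments at the coarse pitch, resamples the coarse
#' mask back to the fine grid, and reports Dice plus detection recall as a
#' function of true particle radius.
#'
#' @param spec a [resolution_bench_spec()].
#' @return list: `dice` (`dice_result`), `recall_by_radius` (data frame:
#'   radius bin mid, n, recall), `n_particles`, `threshold` used by the
#'   coarse segmentation.
#' @export
resolution_benchmark <- function(spec) {
  stopifnot(inherits(spec, "resolution_bench_spec"))
  with_seed(spec$seed, {
    n_px <- round(spec$field_um / spec$hi_res_pixel_um)
    # constant photon flux per tissue area: a fine pixel collects fewer
    # photons, so the box-averaged coarse image carries the same counting
    # statistics as a native coarse acquisition
    flux_scale <- (spec$hi_res_pixel_um / spec$lo_res_pixel_um)^2
    gspec <- granule_field_spec(
      image_shape_px = c(n_px, n_px),
      pixel_size_um = spec$hi_res_pixel_um,
      particle_density_per_mm2 = spec$particle_density_per_mm2,
      radius_mean_um = spec$radius_main_um,
      radius_sd_um = spec$radius_main_sd_um,
      particle_contrast = spec$particle_contrast,
      photons_per_pixel = 1000 * flux_scale,
      count_mode = "fixed", seed = NULL)
    g <- generate_granule_image(gspec)
    parts <- g$truth$particles
    # redraw a sub-resolution size fraction, then restamp on the clean field
    n <- nrow(parts)
    n_sub <- round(spec$subres_fraction * n)
    if (n_sub > 0) {
      sub <- sample.int(n, n_sub)
      parts$radius_um[sub] <- pmax(0.25, rnorm(n_sub, spec$radius_sub_um,
                                               spec$radius_sub_sd_um))
      st <- stamp_particles(g$truth$background,
                            matrix(FALSE, n_px, n_px),
                            parts$x_um, parts$y_um, parts$radius_um,
                            spec$particle_contrast, spec$hi_res_pixel_um,
                            gspec$profile_order)
      lam <- st$img * gspec$photons_per_pixel
      noisy <- matrix(rpois(length(lam), lam), n_px, n_px) /
        gspec$photons_per_pixel
      g$image <- intensity_image(pmax(noisy, 1e-6), spec$hi_res_pixel_um)
      g$truth$mask <- binary_mask(st$mask, spec$hi_res_pixel_um)
      g$truth$particles <- parts
    }

    truth <- if (spec$use_flim_truth) {
      cls <- matrix(2L, n_px, n_px)
      cls[g$truth$mask$mask] <- 1L
      dspec <- decay_sim_spec(seed = NULL)
      stck <- generate_decay_stack(dspec, cls)
      ph <- phasor_transform(stck)
      pp <- phasor_point(400, stck$window_ps, stck$n_bins)
      select_cluster(ph, phasor_ellipse(pp["G"], pp["S"], 0.04, 0.04),
                     spec$hi_res_pixel_um)
    } else g$truth$mask

    f <- as.integer(round(spec$lo_res_pixel_um / spec$hi_res_pixel_um))
    lo <- intensity_image(block_average(g$image$pixels, f),
                          spec$lo_res_pixel_um)
    seg <- segment_lipofuscin(lo, spec$seg_params)
    pred_hi <- binary_mask(nn_upsample(seg$mask$mask, f), spec$hi_res_pixel_um)
    d <- dice(truth, pred_hi)

    # recall by true radius: a particle counts as detected when at least
    # half of its ground-truth disc is covered by the predicted mask
    pm <- pred_hi$mask
    covered <- vapply(seq_len(nrow(parts)), function(p) {
      r <- parts$radius_um[p]
      hx <- parts$x_um[p] / spec$hi_res_pixel_um + 0.5
      hy <- parts$y_um[p] / spec$hi_res_pixel_um + 0.5
      ext <- ceiling(r / spec$hi_res_pixel_um) + 1L
      js <- max(1L, floor(hx - ext)):min(ncol(pm), ceiling(hx + ext))
      is <- max(1L, floor(hy - ext)):min(nrow(pm), ceiling(hy + ext))
      dx <- (js - 0.5) * spec$hi_res_pixel_um - parts$x_um[p]
      dy <- (is - 0.5) * spec$hi_res_pixel_um - parts$y_um[p]
      inside <- outer(dy^2, dx^2, "+") <= r^2
      if (!any(inside)) return(NA)
      mean(pm[is, js][inside]) >= 0.5
    }, logical(1))
    bins <- cut(parts$radius_um, breaks = c(0, 1, 2, 3, 4, Inf))
    rec <- tapply(covered, bins, function(v) mean(v, na.rm = TRUE))
    nb <- tapply(covered, bins, length)
    recall_df <- data.frame(radius_bin = names(rec),
                            n = as.integer(ifelse(is.na(nb), 0, nb)),
                            recall = as.numeric(rec), row.names = NULL)

    list(dice = d, recall_by_radius = recall_df,
         n_particles = nrow(parts), threshold = seg$threshold)
  })
}
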