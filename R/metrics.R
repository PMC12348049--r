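#' Sliding-window specification
#'
#' @param window_um square window side, um (default 100).
#' @param overlap_frac fractional overlap of adjacent windows in `[0, 1)`
#'   (default 0.5, i.e. stride of half a window).
#' @return class `window_spec`.
#' @export
window_spec <- function(window_um = 100, overlap_frac = 0.5) {
  stopifnot_scalar_pos(window_um, "window_um")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)", call. = FALSE)
  structure(list(window_um = window_um, overlap_frac = overlap_frac),
            class = "window_spec")
}

#' Sliding-window lipofuscin metric maps
#'
#' Computes, on a regular grid of square windows (default 100x100 um with
#' 50% overlap), three maps: the mean equivalent radius of the particles
#' whose centroid falls in the window (um; NA when the window holds no
#' particle), the particle number density (count per mm^2 of window area),
#' and the area fraction (% of window pixels that are mask). Partial
#' windows at the border are not evaluated.
#'
#' @param mask a [binary_mask()] from segmentation.
#' @param particles the matching particle table (needs columns x_um, y_um,
#'   equivalent_radius_um).
#' @param win a [window_spec()].
#' @return class `metric_map_set`: matrices `mean_radius_um`,
#'   `number_density_per_mm2`, `area_fraction_pct` (windows-y x windows-x),
#'   plus grid geometry (`origin_px` per axis, `stride_px`, `window_px`,
#'   `pixel_size_um`, `window_um`).
#' @export
metric_maps <- function(mask, particles, win = window_spec()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(win, "window_spec"))
  px <- mask$pixel_size_um
  m <- mask$mask
  w_px <- floor(win$window_um / px)
  if (w_px < 3) stop("window smaller than 3 px", call. = FALSE)
  stride <- max(1L, as.integer(round(w_px * (1 - win$overlap_frac))))
  oy <- seq(1L, nrow(m) - w_px + 1L, by = stride)
  ox <- seq(1L, ncol(m) - w_px + 1L, by = stride)
  if (!length(oy) || !length(ox))
    stop("window larger than the image", call. = FALSE)
  nwy <- length(oy); nwx <- length(ox)

  # area fraction via summed-area table
  sat <- rbind(0, apply(m * 1, 2, cumsum))
  sat <- cbind(0, t(apply(sat, 1, cumsum)))
  wsum <- sat[oy + w_px, ox + w_px, drop = FALSE] -
    sat[oy, ox + w_px, drop = FALSE] -
    sat[oy + w_px, ox, drop = FALSE] + sat[oy, ox, drop = FALSE]
  area_frac <- 100 * wsum / (w_px * w_px)

  count <- matrix(0, nwy, nwx)
  rsum <- matrix(0, nwy, nwx)
  if (nrow(particles) > 0) {
    # pixel indices of particle centroids
    pj <- floor(particles$x_um / px) + 1L
    pi <- floor(particles$y_um / px) + 1L
    for (p in seq_len(nrow(particles))) {
      # windows m with origin o: o <= pi <= o + w - 1
      iy <- which(oy <= pi[p] & pi[p] <= oy + w_px - 1L)
      ix <- which(ox <= pj[p] & pj[p] <= ox + w_px - 1L)
      if (!length(iy) || !length(ix)) next
      count[iy, ix] <- count[iy, ix] + 1
      rsum[iy, ix] <- rsum[iy, ix] + particles$equivalent_radius_um[p]
    }
  }
  win_area_mm2 <- (w_px * px)^2 / 1e6
  density <- count / win_area_mm2
  mean_radius <- ifelse(count > 0, rsum / count, NA_real_)

  structure(list(mean_radius_um = mean_radius,
                 number_density_per_mm2 = density,
                 area_fraction_pct = area_frac,
                 origin_y_px = oy, origin_x_px = ox,
                 stride_px = stride, window_px = w_px,
                 pixel_size_um = px, window_um = win$window_um),
            class = "metric_map_set")
}

metric_names <- c("mean_radius_um", "number_density_per_mm2",
                  "area_fraction_pct")

#' Aggregate metric maps over a region and ROI, then over slices
#'
#' A window contributes when its centre pixel lies in `region & roi` (both
#' optional) and its value is defined. Per-slice means are averaged
#' unweighted across slices. Regions with no valid window yield NA, never
#' zero.
#'
#' @param maps a `metric_map_set` or a list of them (one per slice).
#' @param region optional logical matrix on the pixel grid.
#' @param roi optional logical matrix on the pixel grid.
#' @return data frame with one row per metric: `metric`, `mean`,
#'   `n_windows` (total valid windows), `n_slices`.
#' @export
aggregate_region <- function(maps, region = NULL, roi = NULL) {
  if (inherits(maps, "metric_map_set")) maps <- list(maps)
  per_slice <- lapply(maps, function(mp) {
    cy <- mp$origin_y_px + mp$window_px %/% 2L
    cx <- mp$origin_x_px + mp$window_px %/% 2L
    keep <- matrix(TRUE, length(cy), length(cx))
    if (!is.null(region)) keep <- keep & region[cy, cx, drop = FALSE]
    if (!is.null(roi)) keep <- keep & roi[cy, cx, drop = FALSE]
    vapply(metric_names, function(nm) {
      v <- mp[[nm]][keep]
      v <- v[is.finite(v)]
      c(mean = if (length(v)) mean(v) else NA_real_, n = length(v))
    }, numeric(2))
  })
  means <- t(vapply(per_slice, function(s) s["mean", ], numeric(3)))
  ns <- t(vapply(per_slice, function(s) s["n", ], numeric(3)))
  data.frame(metric = metric_names,
             mean = apply(means, 2, function(v) {
               v <- v[is.finite(v)]
               if (length(v)) mean(v) else NA_real_
             }),
             n_windows = colSums(ns),
             n_slices = length(maps),
             row.names = NULL)
}
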