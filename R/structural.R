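#' Fit scattering coefficients from A-scan depth profiles
#'
#' Per lateral position, the log-intensity of the depth profile is fitted
#' by least squares over the requested depth range; under the
#' single-scattering model `I(z) = I0 exp(-2 mu_s z)` the slope gives
#' `mu_s = -slope / 2`. Pixels with non-positive intensities in the fit
#' range, or negative estimates, are flagged invalid (NA).
#'
#' @param volume 3D array (y, x, depth) of A-scan intensities, or the list
#'   returned by [generate_scattering_volume()].
#' @param depth_pitch_um depth sampling pitch, um (ignored when `volume` is
#'   a generator result carrying its own pitch).
#' @param fit_range_um length-2 depth range (um) used for the fit; default
#'   spans the full depth. At least 5 samples must fall inside.
#' @return list: `mus` matrix (mm^-1, NA where invalid).
#' @export
fit_scattering <- function(volume, depth_pitch_um = NULL,
                           fit_range_um = NULL) {
  if (is.list(volume) && !is.null(volume$volume)) {
    depth_pitch_um <- volume$depth_pitch_um
    volume <- volume$volume
  }
  stopifnot(length(dim(volume)) == 3L, !is.null(depth_pitch_um))
  nz <- dim(volume)[3]
  z_um <- (seq_len(nz) - 0.5) * depth_pitch_um
  if (is.null(fit_range_um)) fit_range_um <- range(z_um)
  sel <- which(z_um >= fit_range_um[1] & z_um <= fit_range_um[2])
  if (length(sel) < 5)
    stop("fit range must contain at least 5 depth samples", call. = FALSE)
  z_mm <- z_um[sel] / 1000
  zc <- z_mm - mean(z_mm)
  denom <- sum(zc^2)
  d <- dim(volume)
  flat <- matrix(volume[, , sel], d[1] * d[2], length(sel))
  bad <- rowSums(flat <= 0) > 0
  logi <- log(pmax(flat, .Machine$double.xmin))
  slope <- as.numeric(logi %*% zc) / denom
  mus <- -slope / 2
  mus[bad | mus < 0] <- NA_real_
  list(mus = matrix(mus, d[1], d[2]))
}

#' Segment gray/white matter and cortical layers from a scattering map
#'
#' White matter is the high-scattering class: the GM/WM split uses either a
#' fixed threshold or a two-class split of the mu_s histogram (k-means
#' midpoint). Within gray matter, the supragranular/infragranular boundary
#' is placed at a configurable fraction of the local cortical thickness
#' along the depth (row) axis. Masks are cleaned by small-object removal.
#'
#' @param mus ScatteringMap matrix (mm^-1, NA invalid) or the list from
#'   [fit_scattering()].
#' @param mus_threshold fixed GM/WM threshold (mm^-1); NULL uses the
#'   two-class histogram split.
#' @param split_frac depth fraction of local GM thickness separating
#'   supragranular (above) from infragranular (below); default 0.5.
#' @param min_object_px connected regions of the WM mask smaller than this
#'   are reassigned (default 9).
#' @param min_separation minimum relative separation of the two histogram
#'   modes; below it the map is declared single-class with a warning.
#' @return class `region_masks`: logical matrices GM, WM, supragranular,
#'   infragranular; the threshold used.
#' @export
segment_regions <- function(mus, mus_threshold = NULL, split_frac = 0.5,
                            min_object_px = 9L, min_separation = 0.1) {
  if (is.list(mus) && !is.null(mus$mus)) mus <- mus$mus
  stopifnot(is.matrix(mus))
  v <- mus[is.finite(mus)]
  if (!length(v)) stop("no valid scattering estimates", call. = FALSE)
  if (is.null(mus_threshold)) {
    if (diff(range(v)) / max(mean(v), 1e-12) < min_separation) {
      warning("scattering map appears single-class; labelling all gray matter")
      mus_threshold <- Inf
    } else {
      km <- kmeans(v, centers = sort(c(min(v), max(v))), iter.max = 50)
      cen <- sort(km$centers[, 1])
      if (diff(cen) / mean(cen) < min_separation) {
        warning("scattering map appears single-class; labelling all gray matter")
        mus_threshold <- Inf
      } else mus_threshold <- mean(cen)
    }
  }
  wm <- !is.na(mus) & mus > mus_threshold
  gm <- !is.na(mus) & !wm
  if (min_object_px > 0 && any(wm) && any(gm)) {
    lab <- label_components(wm, 8L)
    if (max(lab) > 0) {
      small <- which(tabulate(lab[lab > 0], max(lab)) < min_object_px)
      if (length(small)) { gm[lab %in% small] <- TRUE; wm[lab %in% small] <- FALSE }
    }
    lab <- label_components(gm, 8L)
    if (max(lab) > 0) {
      small <- which(tabulate(lab[lab > 0], max(lab)) < min_object_px)
      if (length(small)) { wm[lab %in% small] <- TRUE; gm[lab %in% small] <- FALSE }
    }
  }
  supra <- infra <- matrix(FALSE, nrow(mus), ncol(mus))
  for (j in seq_len(ncol(mus))) {
    rows <- which(gm[, j])
    if (!length(rows)) next
    cut <- rows[1] + split_frac * (rows[length(rows)] - rows[1])
    supra[rows[rows <= cut], j] <- TRUE
    infra[rows[rows > cut], j] <- TRUE
  }
  structure(list(GM = gm, WM = wm, supragranular = supra,
                 infragranular = infra, threshold = mus_threshold),
            class = "region_masks")
}

#' Load crest/sulcus ROI polygons and rasterize them
#'
#' Reads a JSON array of `{name, vertices_um: [[x, y], ...]}` polygon
#' records and rasterizes each onto the pixel grid (a pixel is inside when
#' its centre is inside the polygon; point-in-polygon via `mgcv::in.out`).
#'
#' @param path JSON file path, or an already-parsed list of polygon records.
#' @param image_shape_px integer pair (rows, cols) of the target grid.
#' @param pixel_size_um pixel pitch, um.
#' @return named list of logical masks, one per polygon name.
#' @export
load_roi_polygons <- function(path, image_shape_px, pixel_size_um) {
  polys <- if (is.character(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else path
  if (!length(polys)) stop("empty polygon list", call. = FALSE)
  nr <- image_shape_px[1]; nc <- image_shape_px[2]
  xs <- (seq_len(nc) - 0.5) * pixel_size_um
  ys <- (seq_len(nr) - 0.5) * pixel_size_um
  pts <- cbind(rep(xs, each = nr), rep(ys, times = nc))
  out <- list()
  for (p in polys) {
    v <- p$vertices_um
    if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
    v <- as.matrix(v)
    if (nrow(v) < 3) stop("polygon '", p$name, "' has fewer than 3 vertices",
                          call. = FALSE)
    # close the ring if needed
    if (any(v[1, ] != v[nrow(v), ])) v <- rbind(v, v[1, ])
    inside <- mgcv::in.out(v, pts)
    out[[p$name]] <- matrix(inside, nr, nc)
  }
  out
}
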