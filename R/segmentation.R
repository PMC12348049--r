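#' Segmentation parameters
#'
#' @param kernel_um mean-filter kernel for background normalization, um
#'   (default 50).
#' @param lower_bound floor on the effective ratio-image threshold
#'   (default 1.15); must exceed 1.
#' @param histogram_bins bins for the Huang threshold histogram (default 256).
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#' @param min_area_px components smaller than this are dropped (default 0).
#' @param radius_convention "equivalent-radius" reports sqrt(area/pi);
#'   "equivalent-diameter" reports sqrt(4 area/pi).
#' @return class `segmentation_params`.
#' @export
segmentation_params <- function(kernel_um = 50, lower_bound = 1.15,
                                histogram_bins = 256L,
                                connectivity = c(8L, 4L),
                                min_area_px = 0L,
                                radius_convention = c("equivalent-radius",
                                                      "equivalent-diameter")) {
  connectivity <- as.integer(connectivity)[1]
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  if (lower_bound <= 1) stop("lower_bound must exceed 1", call. = FALSE)
  stopifnot_scalar_pos(kernel_um, "kernel_um")
  structure(list(kernel_um = kernel_um, lower_bound = lower_bound,
                 histogram_bins = as.integer(histogram_bins),
                 connectivity = connectivity,
                 min_area_px = as.integer(min_area_px),
                 radius_convention = match.arg(radius_convention)),
            class = "segmentation_params")
}

#' Divide out the low-frequency background
#'
#' Mean-smooths the image with a physical kernel (mirror padding, kernel
#' size converted to the nearest odd pixel count) and divides the original
#' by the smoothed image, yielding a dimensionless ratio image whose
#' background sits near 1 regardless of illumination.
#'
#' @param img an [intensity_image()].
#' @param kernel_um smoothing kernel size in micrometres; must be at least
#'   twice the pixel pitch and smaller than the image.
#' @return An `intensity_image` of ratios (class kept for pipeline reuse).
#' @export
normalize_background <- function(img, kernel_um = 50) {
  stopifnot(inherits(img, "intensity_image"))
  if (kernel_um < 2 * img$pixel_size_um)
    stop("kernel_um must be at least twice the pixel size", call. = FALSE)
  k <- kernel_px(kernel_um, img$pixel_size_um)
  if (k > min(dim(img$pixels)))
    stop("smoothing kernel larger than the image", call. = FALSE)
  sm <- mean_filter(img$pixels, k)
  ratio <- ifelse(sm > 0, img$pixels / sm, 1)
  intensity_image(ratio, img$pixel_size_um)
}

#' Huang fuzzy threshold
#'
#' Minimum-fuzziness threshold of Huang & Wang: for each candidate bin edge
#' t, pixels take membership u(g) = 1 / (1 + |g - m| / C) to the side of t
#' they fall on (m = that side's mean, C = the value range), and t minimizes
#' the Shannon fuzziness entropy sum h(g) * H(u(g)) with
#' H(u) = -u log u - (1-u) log(1-u). Ties break toward the lowest t.
#'
#' @param values numeric vector or matrix of sample values (an image works).
#' @param bins number of histogram bins over the value range (default 256).
#' @return The threshold, as a bin-edge value on the input scale.
#' @export
huang_threshold <- function(values, bins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("constant input: no threshold exists", call. = FALSE)
  bins <- as.integer(bins)
  h <- tabulate(pmin(bins, 1L + floor((v - rng[1]) / diff(rng) * bins)), bins)
  centers <- rng[1] + (seq_len(bins) - 0.5) * diff(rng) / bins
  edges <- rng[1] + seq_len(bins - 1L) * diff(rng) / bins
  nz <- which(h > 0)
  first <- nz[1]; last <- nz[length(nz)]
  C <- centers[last] - centers[first]
  if (C <= 0) stop("constant input: no threshold exists", call. = FALSE)

  csum <- cumsum(h)
  cwsum <- cumsum(h * centers)
  N <- csum[bins]; W <- cwsum[bins]
  hf <- function(u) {
    s <- numeric(length(u))
    ok <- u > 0 & u < 1
    s[ok] <- -u[ok] * log(u[ok]) - (1 - u[ok]) * log(1 - u[ok])
    s
  }
  cand <- first:(last - 1L)           # threshold separates bins <= t from > t
  ent <- vapply(cand, function(t) {
    n0 <- csum[t]; n1 <- N - n0
    m0 <- cwsum[t] / n0; m1 <- (W - cwsum[t]) / n1
    lo <- seq_len(t); hi <- (t + 1L):bins
    u <- c(1 / (1 + abs(centers[lo] - m0) / C),
           1 / (1 + abs(centers[hi] - m1) / C))
    sum(c(h[lo], h[hi]) * hf(u))
  }, numeric(1))
  edges[cand[which.min(ent)]]
}

# Label connected components. EBImage::bwlabel is 4-connected; 8-connectivity
# is obtained by merging labels that touch diagonally (union-find).
label_components <- function(mask, connectivity = 8L) {
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  if (connectivity == 4L || max(lab) < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]     # down-right diagonal pairs
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]    # down-left diagonal pairs
  pairs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
                 cbind(c_[c_ > 0 & d > 0 & c_ != d], d[c_ > 0 & d > 0 & c_ != d]))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(max(lab))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  newid <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- newid[lab[lab > 0]]
  out
}

# Particle table from a label image.
particle_table <- function(lab, pixel_size_um,
                           radius_convention = "equivalent-radius") {
  n <- max(lab)
  if (n == 0)
    return(data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), x_um = numeric(), y_um = numeric(),
                      equivalent_radius_um = numeric()))
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  area <- tabulate(l, n)
  x_um <- (tapply(cols, l, mean) - 0.5) * pixel_size_um
  y_um <- (tapply(rows, l, mean) - 0.5) * pixel_size_um
  area_um2 <- area * pixel_size_um^2
  r <- sqrt(area_um2 / pi)
  if (radius_convention == "equivalent-diameter") r <- 2 * r
  data.frame(label = seq_len(n), area_px = area, area_um2 = area_um2,
             x_um = as.numeric(x_um), y_um = as.numeric(y_um),
             equivalent_radius_um = as.numeric(r))
}

#' Segment lipofuscin granules
#'
#' Full pipeline: background normalization by mean-filter division, Huang
#' fuzzy thresholding of the ratio image clamped from below at
#' `lower_bound`, connected-component labeling, small-object removal, and a
#' particle table with areas, centroids and equivalent radii.
#'
#' The effective threshold is `max(huang, lower_bound)`: the adaptive value
#' is kept where it is stricter, but the floor guarantees that no pixel
#' within 15% of the normalized background is ever called lipofuscin.
#'
#' @param img an [intensity_image()].
#' @param params a [segmentation_params()].
#' @return list: `mask` ([binary_mask()]), `particles` (data frame),
#'   `threshold` (effective), `huang` (unclamped adaptive value),
#'   `normalized` (ratio image).
#' @export
segment_lipofuscin <- function(img, params = segmentation_params()) {
  stopifnot(inherits(img, "intensity_image"), inherits(params, "segmentation_params"))
  norm <- normalize_background(img, params$kernel_um)
  hu <- tryCatch(huang_threshold(norm$pixels, params$histogram_bins),
                 error = function(e) -Inf)  # constant ratio image: floor rules
  thr <- max(hu, params$lower_bound)
  m <- norm$pixels > thr
  lab <- label_components(m, params$connectivity)
  tab <- particle_table(lab, img$pixel_size_um, params$radius_convention)
  if (params$min_area_px > 0 && nrow(tab) > 0) {
    keep <- tab$area_px >= params$min_area_px
    drop <- tab$label[!keep]
    if (length(drop)) m[lab %in% drop] <- FALSE
    tab <- tab[keep, , drop = FALSE]
    tab$label <- seq_len(nrow(tab))
    rownames(tab) <- NULL
  }
  list(mask = binary_mask(m, img$pixel_size_um), particles = tab,
       threshold = thr, huang = if (is.finite(hu)) hu else NA_real_,
       normalized = norm)
}
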