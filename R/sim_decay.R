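#' TCSPC decay simulation specification
#'
#' Per-pixel photon-count histograms are Poisson draws from mixtures of
#' discretized truncated exponentials. Each pixel class mixes the listed
#' lifetime components with its own simplex weights; lipofuscin is the
#' short-lifetime (~400 ps) class, elastin/collagen the long-lifetime
#' background. No instrument response function is modelled: the target
#' lifetimes are far longer than the time-bin width.
#'
#' @param lifetimes_ps component lifetimes, ps (default 400 and 2000).
#' @param class_fractions list of per-class weight vectors over the
#'   components; each must sum to 1. Names label the classes.
#' @param bin_width_ps TCSPC bin width, ps.
#' @param n_bins number of time bins; the measurement window is
#'   `bin_width_ps * n_bins` (defaults give the assumed 12.5 ns window).
#' @param photons_per_pixel expected total photon count per pixel.
#' @param seed integer seed or NULL.
#' @return class `decay_sim_spec`.
#' @export
decay_sim_spec <- function(lifetimes_ps = c(400, 2000),
                           class_fractions = list(lipofuscin = c(1, 0),
                                                  background = c(0, 1)),
                           bin_width_ps = 12500 / 256,
                           n_bins = 256L,
                           photons_per_pixel = 1e4,
                           seed = NULL) {
  stopifnot(all(lifetimes_ps > 0), n_bins >= 2, bin_width_ps > 0,
            photons_per_pixel >= 0)
  for (f in class_fractions) {
    if (length(f) != length(lifetimes_ps) || any(f < 0) ||
        abs(sum(f) - 1) > 1e-8)
      stop("each class fraction vector must be a simplex over the lifetimes",
           call. = FALSE)
  }
  window_ps <- bin_width_ps * n_bins
  if (window_ps < 3 * max(lifetimes_ps))
    warning("measurement window shorter than 3x the longest lifetime: ",
            "truncation will bias tail fits")
  structure(list(lifetimes_ps = lifetimes_ps,
                 class_fractions = class_fractions,
                 bin_width_ps = bin_width_ps, n_bins = as.integer(n_bins),
                 window_ps = window_ps,
                 photons_per_pixel = photons_per_pixel, seed = seed),
            class = "decay_sim_spec")
}

#' Decay stack container
#'
#' @param counts 3D array (y, x, time bin) of non-negative counts; a matrix
#'   of per-pixel histograms (pixels x bins) is also accepted for 1-row data.
#' @param bin_width_ps bin width, ps.
#' @return class `decay_stack` with fields counts, bin_width_ps, n_bins,
#'   window_ps.
#' @export
decay_stack <- function(counts, bin_width_ps) {
  if (length(dim(counts)) == 2L) counts <- array(counts, c(1, dim(counts)))
  stopifnot(length(dim(counts)) == 3L, all(counts >= 0), bin_width_ps > 0)
  structure(list(counts = counts, bin_width_ps = bin_width_ps,
                 n_bins = dim(counts)[3],
                 window_ps = bin_width_ps * dim(counts)[3]),
            class = "decay_stack")
}

# Probability mass of a truncated exponential (lifetime tau) discretized over
# n bins of width h: p_k proportional to exp(-t_{k-1}/tau) - exp(-t_k/tau),
# normalized over the window (sums to exactly 1).
discretized_exponential <- function(tau_ps, bin_width_ps, n_bins) {
  edges <- (0:n_bins) * bin_width_ps
  q <- exp(-edges[-(n_bins + 1)] / tau_ps) - exp(-edges[-1] / tau_ps)
  q / sum(q)
}

#' Simulate a TCSPC decay stack over a class-label image
#'
#' @param spec a [decay_sim_spec()].
#' @param class_map integer matrix of class labels (1-based index into
#'   `spec$class_fractions`); 0 marks empty pixels (zero counts).
#' @return A [decay_stack()].
#' @export
generate_decay_stack <- function(spec, class_map) {
  stopifnot(inherits(spec, "decay_sim_spec"))
  class_map <- as.matrix(class_map)
  ncls <- length(spec$class_fractions)
  if (any(class_map < 0 | class_map > ncls))
    stop("class_map labels must be in 0..", ncls, call. = FALSE)
  with_seed(spec$seed, {
    nr <- nrow(class_map); nc <- ncol(class_map)
    counts <- array(0L, c(nr, nc, spec$n_bins))
    comp <- vapply(spec$lifetimes_ps, discretized_exponential,
                   numeric(spec$n_bins), bin_width_ps = spec$bin_width_ps,
                   n_bins = spec$n_bins)     # bins x components
    for (cl in seq_len(ncls)) {
      idx <- which(class_map == cl)
      if (!length(idx)) next
      p <- as.numeric(comp %*% spec$class_fractions[[cl]])
      lam <- spec$photons_per_pixel * p
      draws <- matrix(rpois(length(idx) * spec$n_bins,
                            rep(lam, each = length(idx))),
                      nrow = length(idx))
      for (k in seq_len(spec$n_bins)) {
        page <- counts[, , k]
        page[idx] <- draws[, k]
        counts[, , k] <- page
      }
    }
    decay_stack(counts, spec$bin_width_ps)
  })
}

#' Simulate an A-scan scattering volume with known region masks
#'
#' Depth profiles follow the single-scattering model
#' `I(z) = I0 * exp(-2 mu_s z)` with optional multiplicative Gaussian noise.
#' The lateral field is split into regions by a label map (default: left
#' half gray matter, right half white matter); white matter must scatter
#' more strongly than gray matter.
#'
#' @param gm_mus,wm_mus scattering coefficients, mm^-1 (wm_mus > gm_mus).
#' @param shape integer triple (rows, cols, depth samples).
#' @param depth_pitch_um depth sampling pitch, um.
#' @param region_map optional integer matrix (1 = GM, 2 = WM); default
#'   splits columns in half.
#' @param noise_sd relative multiplicative noise sd (0 = noise free).
#' @param i0 surface intensity.
#' @param seed integer seed or NULL.
#' @return list: `volume` (3D array y,x,z), `depth_pitch_um`, `masks`
#'   (list of logical GM/WM matrices), `mus` (true map, mm^-1).
#' @export
generate_scattering_volume <- function(gm_mus = 6, wm_mus = 12,
                                       shape = c(32L, 32L, 40L),
                                       depth_pitch_um = 4,
                                       region_map = NULL,
                                       noise_sd = 0, i0 = 1000, seed = NULL) {
  if (wm_mus <= gm_mus)
    stop("wm_mus must exceed gm_mus (white matter scatters more strongly)",
         call. = FALSE)
  shape <- as.integer(shape)
  if (length(shape) != 3L || shape[3] < 2L)
    stop("shape must give at least 2 depth samples", call. = FALSE)
  if (is.null(region_map)) {
    region_map <- matrix(1L, shape[1], shape[2])
    region_map[, seq_len(shape[2]) > shape[2] / 2] <- 2L
  }
  stopifnot(all(dim(region_map) == shape[1:2]))
  with_seed(seed, {
    mus_map <- matrix(c(gm_mus, wm_mus)[region_map], shape[1], shape[2])
    z_mm <- ((seq_len(shape[3]) - 0.5) * depth_pitch_um) / 1000
    vol <- array(0, shape)
    for (k in seq_len(shape[3]))
      vol[, , k] <- i0 * exp(-2 * mus_map * z_mm[k])
    if (noise_sd > 0)
      vol <- vol * (1 + array(rnorm(length(vol), 0, noise_sd), shape))
    vol[vol < 0] <- 0
    list(volume = vol, depth_pitch_um = depth_pitch_um,
         masks = list(GM = region_map == 1L, WM = region_map == 2L),
         mus = mus_map)
  })
}
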