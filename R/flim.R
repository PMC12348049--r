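#' Phasor transform of a TCSPC decay stack
#'
#' Maps each pixel's decay histogram to phasor coordinates
#' `G = sum c_k cos(n w t_k) / sum c_k` and `S = sum c_k sin(n w t_k) / sum c_k`
#' with `w = 2 pi / window` (fundamental harmonic of the measurement window)
#' and `t_k` the bin centres. Monoexponential decays fall on the universal
#' semicircle `(G - 1/2)^2 + S^2 = 1/4` up to discretization; mixtures fall
#' on the chord between their components. Pixels with zero total counts are
#' flagged invalid (NA).
#'
#' @param stack a [decay_stack()].
#' @param harmonic positive integer harmonic (default 1).
#' @return class `phasor_map`: G, S (matrices), total_counts,
#'   omega_rad_per_ps, harmonic.
#' @export
phasor_transform <- function(stack, harmonic = 1L) {
  stopifnot(inherits(stack, "decay_stack"))
  harmonic <- as.integer(harmonic)
  if (harmonic < 1L) stop("harmonic must be >= 1", call. = FALSE)
  d <- dim(stack$counts)
  omega <- 2 * pi / stack$window_ps
  tk <- (seq_len(stack$n_bins) - 0.5) * stack$bin_width_ps
  cvec <- cos(harmonic * omega * tk); svec <- sin(harmonic * omega * tk)
  flat <- matrix(stack$counts, d[1] * d[2], d[3])
  tot <- rowSums(flat)
  G <- as.numeric(flat %*% cvec) / tot
  S <- as.numeric(flat %*% svec) / tot
  G[tot == 0] <- NA_real_; S[tot == 0] <- NA_real_
  structure(list(G = matrix(G, d[1], d[2]), S = matrix(S, d[1], d[2]),
                 total_counts = matrix(tot, d[1], d[2]),
                 omega_rad_per_ps = omega, harmonic = harmonic),
            class = "phasor_map")
}

#' Phasor coordinates of a discretized monoexponential decay
#'
#' Closed form for the binned, window-truncated exponential: the expected
#' phasor of a noise-free decay with lifetime `tau_ps` as measured in
#' `n_bins` bins over `window_ps`. Useful for placing cluster ellipses at a
#' target lifetime.
#'
#' @param tau_ps lifetime, ps.
#' @param window_ps measurement window, ps.
#' @param n_bins number of bins.
#' @param harmonic harmonic number.
#' @return named vector c(G =, S =).
#' @export
phasor_point <- function(tau_ps, window_ps, n_bins, harmonic = 1L) {
  p <- discretized_exponential(tau_ps, window_ps / n_bins, n_bins)
  omega <- 2 * pi / window_ps
  tk <- (seq_len(n_bins) - 0.5) * window_ps / n_bins
  c(G = sum(p * cos(harmonic * omega * tk)),
    S = sum(p * sin(harmonic * omega * tk)))
}

#' Elliptical cluster region on the phasor plot
#'
#' @param g0,s0 centre.
#' @param a,b semi-axes (must be positive).
#' @param angle_rad rotation of the a-axis from the G axis.
#' @return class `phasor_ellipse`.
#' @export
phasor_ellipse <- function(g0, s0, a, b, angle_rad = 0) {
  stopifnot_scalar_pos(a, "a"); stopifnot_scalar_pos(b, "b")
  structure(list(g0 = g0, s0 = s0, a = a, b = b, angle_rad = angle_rad),
            class = "phasor_ellipse")
}

#' Back-annotate a phasor cluster into image space
#'
#' Selects the pixels whose (G, S) coordinates fall inside the rotated
#' ellipse (normalized quadratic form <= 1); this is the back-annotation
#' step that turns a phasor-plot cluster into an image mask.
#'
#' @param phasor a `phasor_map`.
#' @param ellipse a [phasor_ellipse()].
#' @param pixel_size_um pixel pitch recorded in the returned mask.
#' @return A [binary_mask()]; invalid (zero-count) pixels are FALSE.
#' @export
select_cluster <- function(phasor, ellipse, pixel_size_um = 1) {
  stopifnot(inherits(phasor, "phasor_map"), inherits(ellipse, "phasor_ellipse"))
  dg <- phasor$G - ellipse$g0
  ds <- phasor$S - ellipse$s0
  ca <- cos(ellipse$angle_rad); sa <- sin(ellipse$angle_rad)
  u <- dg * ca + ds * sa
  v <- -dg * sa + ds * ca
  inside <- (u / ellipse$a)^2 + (v / ellipse$b)^2 <= 1
  inside[is.na(inside)] <- FALSE
  binary_mask(inside, pixel_size_um)
}

#' Pool decays over a pixel mask
#'
#' Sums the per-pixel histograms of all masked pixels into one
#' high-photon-count decay curve, the standard trick for fitting weak
#' per-pixel signals after phasor selection.
#'
#' @param stack a [decay_stack()].
#' @param mask logical matrix or [binary_mask()] matching the stack's field.
#' @return numeric vector of pooled counts (length `n_bins`).
#' @export
pool_decay <- function(stack, mask) {
  stopifnot(inherits(stack, "decay_stack"))
  if (inherits(mask, "binary_mask")) mask <- mask$mask
  d <- dim(stack$counts)
  stopifnot(all(dim(mask) == d[1:2]))
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  flat <- matrix(stack$counts, d[1] * d[2], d[3])
  colSums(flat[as.logical(mask), , drop = FALSE])
}

# Negative Poisson log-likelihood of counts under the normalized model p
# (sums to 1) with total intensity profiled out (N-hat = sum of counts).
poisson_nll <- function(counts, p) {
  N <- sum(counts)
  lam <- N * p
  ok <- lam > 0
  sum(lam[ok]) - sum(counts[ok] * log(lam[ok]))
}

#' Poisson maximum-likelihood decay fitting
#'
#' Fits a 1- or 2-component truncated-exponential mixture to a decay
#' histogram by maximizing the Poisson log-likelihood, the correct noise
#' model for photon-counting data. The per-bin model is
#' `lambda_k = N * sum_i alpha_i p_i(k)` with `p_i` the discretized
#' exponential of lifetime `tau_i` normalized over the window, and `N`
#' profiled out as the total count. A multi-start grid over lifetimes
#' avoids local optima; for two components the result is reported in
#' ascending lifetime order.
#'
#' @param histogram numeric vector of per-bin counts.
#' @param n_components 1 or 2.
#' @param bin_width_ps bin width, ps.
#' @param window_ps measurement window, ps; defaults to
#'   `bin_width_ps * length(histogram)`.
#' @return class `lifetime_fit`: `tau_ps` (ascending), `alpha` (simplex),
#'   `tau_mean_ps` (amplitude-weighted), `nll`, `chisq_reduced`,
#'   `converged`, `total_counts`.
#' @export
fit_decay_ml <- function(histogram, n_components = 1L,
                         bin_width_ps, window_ps = bin_width_ps * length(histogram)) {
  n_components <- as.integer(n_components)
  stopifnot(n_components %in% c(1L, 2L), all(histogram >= 0))
  nb <- length(histogram)
  tot <- sum(histogram)
  if (tot == 0) stop("empty histogram", call. = FALSE)
  if (tot < 100)
    warning("fewer than 100 photons in the histogram: fit unreliable")

  pfun <- function(tau) discretized_exponential(tau, bin_width_ps, nb)
  tau_lo <- bin_width_ps / 5
  tau_hi <- 3 * window_ps
  grid <- exp(seq(log(max(tau_lo, bin_width_ps / 2)), log(tau_hi), length.out = 25))

  if (n_components == 1L) {
    nll1 <- function(lt) poisson_nll(histogram, pfun(exp(lt)))
    g_nll <- vapply(log(grid), nll1, numeric(1))
    i <- which.min(g_nll)
    lo <- log(grid[max(1, i - 1)]); hi <- log(grid[min(length(grid), i + 1)])
    opt <- optimize(nll1, c(lo, hi))
    tau <- exp(opt$minimum); alpha <- 1
    nll <- opt$objective
    converged <- TRUE
    npar <- 2  # tau + amplitude
    lam <- tot * pfun(tau)
  } else {
    nll2 <- function(par) {
      t1 <- exp(par[1]); t2 <- exp(par[2])
      a <- 1 / (1 + exp(-par[3]))
      poisson_nll(histogram, a * pfun(t1) + (1 - a) * pfun(t2))
    }
    starts <- expand.grid(t1 = grid[seq(2, 24, by = 5)],
                          t2 = grid[seq(3, 25, by = 5)])
    starts <- starts[starts$t1 < starts$t2, ]
    best <- NULL
    for (r in seq_len(nrow(starts))) {
      fit <- tryCatch(
        optim(c(log(starts$t1[r]), log(starts$t2[r]), 0), nll2,
              method = "Nelder-Mead",
              control = list(maxit = 800, reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("two-component fit failed from every start", call. = FALSE)
    # polish the best start
    best <- optim(best$par, nll2, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
    taus <- exp(best$par[1:2])
    a <- 1 / (1 + exp(-best$par[3]))
    alpha <- c(a, 1 - a)
    ord <- order(taus)
    tau <- taus[ord]; alpha <- alpha[ord]
    nll <- best$value
    converged <- best$convergence == 0
    if (!converged)
      warning("two-component ML fit did not converge; result flagged")
    npar <- 4
    lam <- tot * (alpha[1] * pfun(tau[1]) + alpha[2] * pfun(tau[2]))
  }
  ok <- lam > 1e-12
  chisq <- sum((histogram[ok] - lam[ok])^2 / lam[ok]) / max(1, sum(ok) - npar)
  structure(list(tau_ps = tau, alpha = alpha,
                 tau_mean_ps = sum(alpha * tau),
                 nll = nll, chisq_reduced = chisq,
                 converged = converged, total_counts = tot),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("lifetime_fit: tau = %s ps (alpha = %s), tau_mean = %.1f ps, red. chi2 = %.3f%s\n",
              paste(sprintf("%.1f", x$tau_ps), collapse = "/"),
              paste(sprintf("%.2f", x$alpha), collapse = "/"),
              x$tau_mean_ps, x$chisq_reduced,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Per-pixel mean-lifetime image
#'
#' Fits each pixel with at least `min_counts` photons by Poisson ML and
#' returns the amplitude-weighted mean lifetime; pixels below the count
#' floor are NA (invalid), never zero.
#'
#' @param stack a [decay_stack()].
#' @param n_components 1 or 2 components per pixel.
#' @param min_counts minimum photons for a valid fit (default 100).
#' @return numeric matrix of mean lifetimes (ps) with NA where invalid.
#' @export
lifetime_image <- function(stack, n_components = 1L, min_counts = 100) {
  stopifnot(inherits(stack, "decay_stack"))
  d <- dim(stack$counts)
  flat <- matrix(stack$counts, d[1] * d[2], d[3])
  tot <- rowSums(flat)
  out <- rep(NA_real_, d[1] * d[2])
  for (i in which(tot >= min_counts)) {
    fit <- suppressWarnings(
      fit_decay_ml(flat[i, ], n_components, stack$bin_width_ps, stack$window_ps))
    out[i] <- fit$tau_mean_ps
  }
  matrix(out, d[1], d[2])
}

#' Refine a phasor cluster ellipse toward a target mean lifetime
#'
#' Grid search over ellipse centre and semi-axes: each candidate selects a
#' pixel set, whose pooled decay is ML-fitted; the objective trades
#' closeness of the fitted mean lifetime to `target_ps` against the reduced
#' chi-square of the fit (weighted sum, weights configurable). Mirrors the
#' iterative manual refinement of a phasor ROI toward the lipofuscin
#' cluster.
#'
#' @param phasor a `phasor_map`.
#' @param stack the matching [decay_stack()].
#' @param init a [phasor_ellipse()] starting region.
#' @param target_ps target mean lifetime (default 400).
#' @param n_components components for the pooled fit.
#' @param w_tau,w_chisq objective weights for |tau - target| (per ps) and
#'   reduced chi-square.
#' @param center_steps,axis_factors search grid: centre offsets (in phasor
#'   units) and multiplicative axis factors.
#' @return list: `ellipse` (best), `fit` (pooled fit), `objective`.
#' @export
refine_phasor_ellipse <- function(phasor, stack, init, target_ps = 400,
                                  n_components = 1L,
                                  w_tau = 1, w_chisq = 10,
                                  center_steps = c(-0.02, 0, 0.02),
                                  axis_factors = c(0.5, 1, 2)) {
  stopifnot(inherits(init, "phasor_ellipse"))
  best <- NULL
  for (dg in center_steps) for (ds in center_steps)
    for (fa in axis_factors) for (fb in axis_factors) {
      ell <- phasor_ellipse(init$g0 + dg, init$s0 + ds,
                            init$a * fa, init$b * fb, init$angle_rad)
      m <- select_cluster(phasor, ell)
      if (!any(m$mask)) next
      fit <- suppressWarnings(
        fit_decay_ml(pool_decay(stack, m), n_components,
                     stack$bin_width_ps, stack$window_ps))
      obj <- w_tau * abs(fit$tau_mean_ps - target_ps) + w_chisq * fit$chisq_reduced
      if (is.null(best) || obj < best$objective)
        best <- list(ellipse = ell, fit = fit, objective = obj)
    }
  if (is.null(best)) stop("no candidate ellipse selected any pixels", call. = FALSE)
  best
}
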