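#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim optimize rpois rnorm runif rbinom lm coef kmeans
#'   median rlnorm quantile complete.cases setNames
#' @importFrom utils write.csv read.csv combn
NULL

# Run expr with a temporarily fixed RNG state; NULL seed leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a reproducible substream seed from a master seed and a stage label.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name), call. = FALSE)
  invisible(x)
}

# Odd mean-filter kernel size in pixels for a physical kernel size in microns.
kernel_px <- function(kernel_um, pixel_size_um) {
  k <- round(kernel_um / pixel_size_um)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

# Mirror (symmetric, edge included) padding of a matrix by `pad` pixels each side.
mirror_pad <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  if (pad >= nr || pad >= nc)
    stop("padding exceeds image size; kernel larger than image", call. = FALSE)
  if (pad == 0) return(m)
  ri <- c(pad:1, 1:nr, nr:(nr - pad + 1))
  ci <- c(pad:1, 1:nc, nc:(nc - pad + 1))
  m[ri, ci, drop = FALSE]
}

# Box (mean) filter with mirror padding, via a summed-area table. O(n) in pixels.
mean_filter <- function(m, k) {
  if (k %% 2L != 1L) stop("kernel size must be odd", call. = FALSE)
  if (k == 1L) return(m)
  pad <- (k - 1L) %/% 2L
  p <- mirror_pad(m, pad)
  # summed-area table with a zero row/col prepended
  sat <- rbind(0, apply(p, 2, cumsum))
  sat <- cbind(0, t(apply(sat, 1, cumsum)))
  nr <- nrow(m); nc <- ncol(m)
  i2 <- (1 + 2 * pad) + 0:(nr - 1); i1 <- 0:(nr - 1)
  j2 <- (1 + 2 * pad) + 0:(nc - 1); j1 <- 0:(nc - 1)
  s <- sat[i2 + 1, j2 + 1, drop = FALSE] - sat[i1 + 1, j2 + 1, drop = FALSE] -
    sat[i2 + 1, j1 + 1, drop = FALSE] + sat[i1 + 1, j1 + 1, drop = FALSE]
  s / (k * k)
}

# Block (box) average downsampling by an integer factor; crops any remainder.
block_average <- function(m, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  nr <- (nrow(m) %/% factor) * factor
  nc <- (ncol(m) %/% factor) * factor
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- array(m, c(factor, nr %/% factor, factor, nc %/% factor))
  apply(a, c(2, 4), mean)
}

# Nearest-neighbour integer upsampling (each pixel replicated factor x factor).
nn_upsample <- function(m, factor) {
  factor <- as.integer(factor)
  m[rep(seq_len(nrow(m)), each = factor), rep(seq_len(ncol(m)), each = factor),
    drop = FALSE]
}
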