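#' Sulcus-over-crest ratios
#'
#' Within-subject normalization: for each subject, metric and tissue, the
#' sulcus-mean divided by the crest-mean. Because disease-related
#' lipofuscin accumulation localizes to sulci while crests are unchanged,
#' the ratio cancels subject-level variation in absolute lipofuscin load
#' and imaging settings. Rows with missing or non-positive crest means are
#' flagged NA.
#'
#' @param summaries data frame with columns `subject`, `group`, `metric`,
#'   `tissue`, `side` ("crest"/"sulcus") and `mean`.
#' @return data frame with columns subject, group, metric, tissue, socr.
#' @export
socr <- function(summaries) {
  need <- c("subject", "group", "metric", "tissue", "side", "mean")
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  crest <- summaries[summaries$side == "crest", ]
  sulcus <- summaries[summaries$side == "sulcus", ]
  key <- function(d) paste(d$subject, d$metric, d$tissue, sep = "\r")
  i <- match(key(sulcus), key(crest))
  cm <- crest$mean[i]
  out <- data.frame(subject = sulcus$subject, group = sulcus$group,
                    metric = sulcus$metric, tissue = sulcus$tissue,
                    socr = ifelse(!is.na(cm) & cm > 0, sulcus$mean / cm,
                                  NA_real_),
                    row.names = NULL)
  out
}

# U statistic of sample x vs y from average ranks (ties shared).
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Exact two-tailed Mann-Whitney test
#'
#' For small samples (`n1 + n2 <= max_exact`) the null distribution of U is
#' built by full enumeration of all `choose(n1 + n2, n1)` group assignments
#' of the observed pooled values (average ranks, so ties are handled by
#' enumerating the observed multiset); the two-tailed p-value is
#' `2 * Pr(U' <= min(U, n1 n2 - U))`, capped at 1 (no mid-p). Larger
#' samples use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @param max_exact largest `n1 + n2` for exact enumeration (default 12,
#'   covering 5 vs 5).
#' @return class `group_comparison`: `U`, `p`, `method`, `n`, medians and
#'   means per sample.
#' @export
mann_whitney_exact <- function(x, y, max_exact = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty", call. = FALSE)
  U <- u_statistic(x, y)
  pool <- c(x, y)
  if (n1 + n2 <= max_exact) {
    r <- rank(pool)
    sets <- combn(n1 + n2, n1)
    r1 <- colSums(matrix(r[sets], nrow = n1))
    Uall <- r1 - n1 * (n1 + 1) / 2
    ucrit <- min(U, n1 * n2 - U)
    p <- min(1, 2 * mean(Uall <= ucrit + 1e-9))
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(pool)
    tiecor <- sum(ties^3 - ties)
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tiecor / (N * (N - 1))))
    if (sigma == 0) { p <- 1 } else {
      z <- (abs(U - mu) - 0.5) / sigma   # continuity corrected
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal approximation (tie corrected)"
  }
  structure(list(U = U, p = p, method = method, n = c(n1, n2),
                 median = c(stats::median(x), stats::median(y)),
                 mean = c(mean(x), mean(y))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s): U = %.1f, two-tailed p = %.5g (n = %d vs %d)\n",
              x$method, x$U, x$p, x$n[1], x$n[2]))
  invisible(x)
}

#' Linear regression of a lipofuscin metric against age
#'
#' Ordinary least squares of per-subject metric values on age; reports
#' slope (metric units per year), intercept and R-squared. With constant
#' values the slope is 0 and R-squared is reported as 0.
#'
#' @param values per-subject metric values.
#' @param ages matching ages in years.
#' @return list: slope, intercept, r_squared, n.
#' @export
age_regression <- function(values, ages) {
  ok <- is.finite(values) & is.finite(ages)
  values <- values[ok]; ages <- ages[ok]
  if (length(values) < 3) stop("need at least 3 subjects", call. = FALSE)
  fit <- lm(values ~ ages)
  ss_tot <- sum((values - mean(values))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(fit$residuals^2) / ss_tot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = length(values))
}

#' Full grid of pairwise group comparisons
#'
#' Runs the exact two-tailed Mann-Whitney test for every group pair within
#' every metric x region cell of a long results table. No multiple-testing
#' correction is applied by default; Benjamini-Hochberg adjusted p-values
#' can be added with `adjust = "BH"`.
#'
#' @param results long data frame with columns `subject`, `group`, `metric`,
#'   `region` and `value`.
#' @param adjust "none" (default) or "BH".
#' @return data frame: metric, region, group1, group2, n1, n2, U, p (and
#'   p_adj when requested). With fewer than two groups an empty table is
#'   returned with a warning.
#' @export
comparison_table <- function(results, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  need <- c("subject", "group", "metric", "region", "value")
  if (!all(need %in% names(results)))
    stop("results must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  groups <- sort(unique(as.character(results$group)))
  empty <- data.frame(metric = character(), region = character(),
                      group1 = character(), group2 = character(),
                      n1 = integer(), n2 = integer(),
                      U = numeric(), p = numeric())
  if (length(groups) < 2) {
    warning("fewer than two groups: no comparisons possible")
    return(empty)
  }
  pairs <- combn(groups, 2)
  rows <- list()
  for (m in unique(results$metric)) for (rg in unique(results$region)) {
    cell <- results[results$metric == m & results$region == rg, ]
    for (k in seq_len(ncol(pairs))) {
      g1 <- pairs[1, k]; g2 <- pairs[2, k]
      v1 <- cell$value[cell$group == g1]
      v2 <- cell$value[cell$group == g2]
      v1 <- v1[is.finite(v1)]; v2 <- v2[is.finite(v2)]
      if (!length(v1) || !length(v2)) next
      mw <- mann_whitney_exact(v1, v2)
      rows[[length(rows) + 1]] <- data.frame(
        metric = m, region = rg, group1 = g1, group2 = g2,
        n1 = length(v1), n2 = length(v2), U = mw$U, p = mw$p)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (adjust == "BH" && nrow(out)) out$p_adj <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
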