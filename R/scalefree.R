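#' Logarithmically bin a cluster-size sample
#'
#' Histogram with geometrically growing bins `[base^k, base^(k+1))`
#' covering the size range, normalized per unit size:
#' `density = count / (bin_width * n_sizes)`, so that
#' `sum(density * width) = 1`. This is the standard stabilizer for
#' heavy-tailed size distributions plotted in log-log coordinates.
#'
#' @param sizes vector of positive sizes (voxel counts).
#' @param base bin growth factor, > 1 (default 2).
#' @return an object of class `size_distribution`: a tibble with columns
#'   `bin_lo`, `bin_hi`, `bin_center` (geometric mean of the edges),
#'   `count`, `density`; attribute `n_sizes`.
#' @export
log_bin <- function(sizes, base = 2) {
  sizes <- as.numeric(sizes)
  if (!length(sizes)) abort("`sizes` is empty.")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    abort("`sizes` must be positive and finite.")
  if (!(is.numeric(base) && length(base) == 1L && base > 1))
    abort("`base` must be a scalar > 1.")
  k_lo <- floor(log(min(sizes)) / log(base))
  k_hi <- floor(log(max(sizes)) / log(base))
  # guard against log round-off at exact powers of the base
  while (base^k_lo > min(sizes)) k_lo <- k_lo - 1
  while (base^(k_hi + 1) <= max(sizes)) k_hi <- k_hi + 1
  edges <- base^(k_lo:(k_hi + 1))
  counts <- tabulate(findInterval(sizes, edges), nbins = length(edges) - 1)
  width <- diff(edges)
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    bin_center = sqrt(edges[-length(edges)] * edges[-1]),
    count = as.integer(counts),
    density = counts / (width * length(sizes)),
    # edge bins that cover the observed range only partially understate
    # the density; the tail fit skips them
    complete = edges[-length(edges)] >= min(sizes) &
      edges[-1] <= max(sizes) + 1)
  attr(out, "n_sizes") <- length(sizes)
  class(out) <- c("size_distribution", class(out))
  out
}

#' Fit the power-law tail of a size distribution
#'
#' Ordinary least squares of `log(density)` on `log(bin_center)` over the
#' occupied bins whose centre is at least `s_min_fit` (the distribution's
#' turning point; ~100 voxels for HRC sizes). For a density proportional
#' to `s^(-alpha)` the fitted slope is `-alpha`. If the distribution
#' carries a `complete` column (see [log_bin()]), bins that only partially
#' cover the observed size range are excluded, since their understated
#' density would bias the slope.
#'
#' @param dist a [log_bin()] result, or any data frame with `bin_center`
#'   and `density` columns.
#' @param s_min_fit tail start (same units as the sizes; default 100).
#' @return an object of class `powerlaw_fit` with fields `alpha`,
#'   `s_min_fit`, `r_squared`, `stderr_alpha`, `n_bins_used`.
#' @export
fit_powerlaw <- function(dist, s_min_fit = 100) {
  if (!all(c("bin_center", "density") %in% names(dist)))
    abort("`dist` needs `bin_center` and `density` columns.")
  use <- dist$density > 0 & dist$bin_center >= s_min_fit
  if ("complete" %in% names(dist)) use <- use & dist$complete
  if (sum(use) < 3L)
    abort(sprintf(
      "tail too short: %d occupied bins with center >= %g (need >= 3).",
      sum(use), s_min_fit))
  lx <- log(dist$bin_center[use])
  ly <- log(dist$density[use])
  fit <- stats::lm(ly ~ lx)
  # analytic densities fit exactly; silence summary.lm's perfect-fit note
  sm <- suppressWarnings(summary(fit))
  structure(
    list(alpha = -unname(stats::coef(fit)[2]),
         s_min_fit = s_min_fit,
         r_squared = sm$r.squared,
         stderr_alpha = unname(sm$coefficients[2, 2]),
         n_bins_used = sum(use)),
    class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> alpha = %.3f (SE %.3f), tail s >= %g, %d bins, R^2 = %.3f\n",
    x$alpha, x$stderr_alpha, x$s_min_fit, x$n_bins_used, x$r_squared))
  invisible(x)
}

#' @method tidy powerlaw_fit
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(term = "alpha", estimate = x$alpha,
                 std.error = x$stderr_alpha)
}

#' @method glance powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, s_min_fit = x$s_min_fit,
                 r.squared = x$r_squared, stderr_alpha = x$stderr_alpha,
                 n_bins_used = x$n_bins_used)
}

#' Maximum-likelihood power-law exponent (cross-check)
#'
#' Continuous-tail Hill estimator `1 + n / sum(log(s / s_min))` over sizes
#' `>= s_min`. This is not the binned-regression estimate the cluster
#' analysis reports; it is provided as an independent cross-check.
#'
#' @param sizes positive sizes.
#' @param s_min tail start.
#' @return scalar alpha estimate.
#' @export
fit_powerlaw_mle <- function(sizes, s_min = 100) {
  s <- sizes[sizes >= s_min]
  if (length(s) < 10L) abort("too few tail sizes for the MLE cross-check.")
  1 + length(s) / sum(log(s / s_min))
}

#' Correlations among exponent, cluster count, and mean size
#'
#' Pearson correlations (with two-sided p-values) among the per-participant
#' power-law exponent, HRC count, and mean HRC size. Zero-variance metrics
#' are flagged as undefined rather than reported as 0.
#'
#' @param cohort_metrics data frame with columns `alpha`, `n_clusters`,
#'   `mean_size` (one row per participant).
#' @return tibble: `var1`, `var2`, `estimate`, `p_value`, `defined`.
#' @export
exponent_metric_relations <- function(cohort_metrics) {
  need <- c("alpha", "n_clusters", "mean_size")
  if (!all(need %in% names(cohort_metrics)))
    abort("`cohort_metrics` needs alpha, n_clusters, mean_size columns.")
  cm <- cohort_metrics[stats::complete.cases(cohort_metrics[need]), need]
  if (nrow(cm) < 4L) abort("need >= 4 participants with valid fits.")
  pairs <- utils::combn(need, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    x <- cm[[p[1]]]; y <- cm[[p[2]]]
    if (sd(x) == 0 || sd(y) == 0)
      return(tibble::tibble(var1 = p[1], var2 = p[2],
                            estimate = NA_real_, p_value = NA_real_,
                            defined = FALSE))
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble::tibble(var1 = p[1], var2 = p[2],
                   estimate = unname(ct$estimate),
                   p_value = ct$p.value, defined = TRUE)
  })
}
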