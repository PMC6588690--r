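#' Kendall's coefficient of concordance
#'
#' Agreement of K time series over N time points, computed from within-row
#' ranks (ties receive average ranks; no tie-correction term, so heavy
#' ties shrink W below 1):
#' \deqn{W = \frac{\sum_{i=1}^{N} R_i^2 - N \bar R^2}{\frac{1}{12} K^2 (N^3 - N)}}
#' where \eqn{R_i} is the sum over the K series of the rank held at time
#' point i and \eqn{\bar R} its mean. W = 1 for identical rank orders and
#' ~0 for unrelated series.
#'
#' @param series K x N numeric matrix: each row one time series, ranked
#'   along time.
#' @return scalar W.
#' @export
kendalls_w <- function(series) {
  series <- as.matrix(series)
  K <- nrow(series)
  N <- ncol(series)
  if (K < 2L || N < 2L) abort("need K >= 2 series and N >= 2 time points.")
  ranks <- t(apply(series, 1L, rank, ties.method = "average"))
  Ri <- colSums(ranks)
  (sum(Ri^2) - N * mean(Ri)^2) / (K^2 * (N^3 - N) / 12)
}

#' Voxel-wise ReHo map
#'
#' For every in-mask voxel, gathers the in-mask members of its 3x3x3
#' neighbourhood (the voxel plus up to 26 neighbours) and computes
#' [kendalls_w()] with K equal to the member count, provided the count
#' reaches `min_neighbors`; otherwise the voxel is marked undefined (`NA`).
#' The default `min_neighbors = 27` keeps only voxels with a complete
#' neighbourhood, avoiding K-heterogeneity at mask edges; lower it (>= 7)
#' to mirror toolboxes that compute shrinking-neighbourhood edge values.
#'
#' @param series a preprocessed [bold_series()].
#' @param mask 3D logical array on the series grid.
#' @param min_neighbors minimum in-mask neighbourhood size (including the
#'   centre voxel) for a defined value; 7..27.
#' @return a [reho_map()].
#' @export
compute_reho <- function(series, mask, min_neighbors = 27L) {
  stopifnot(inherits(series, "bold_series"))
  d <- dim(series$data)
  if (!identical(dim(mask), d[1:3])) abort("mask grid mismatch.")
  if (!any(mask)) abort("mask is empty.")
  min_neighbors <- as.integer(min_neighbors)
  if (min_neighbors < 2L || min_neighbors > 27L)
    abort("`min_neighbors` must be in 2..27.")
  nt <- d[4]
  dat <- matrix(series$data, nrow = prod(d[1:3]), ncol = nt)
  vals <- .reho_map_cpp(dat, as.integer(d[1:3]), as.logical(mask),
                        min_neighbors)
  vals <- pmin(pmax(vals, 0), 1)   # clamp roundoff at the [0,1] boundary
  reho_map(array(vals, d[1:3]), mask = array(mask, d[1:3]),
           K_policy = list(min_neighbors = min_neighbors),
           resolution_mm = series$voxel_size_mm)
}

#' Nearest-neighbour resampling of a ReHo map
#'
#' Regrids a map to a new voxel size by nearest-neighbour lookup (each
#' target voxel centre takes the value of the nearest source voxel).
#' Contiguity of suprathreshold regions is preserved under integer
#' upsampling factors. Cluster metrics are computed on the native grid by
#' default; this resample exists for visualization and cross-grid
#' comparisons.
#'
#' @param map a [reho_map()].
#' @param target_mm numeric length-3, target voxel size in mm.
#' @return a resampled [reho_map()].
#' @export
resample_nearest <- function(map, target_mm) {
  stopifnot(inherits(map, "reho_map"))
  target_mm <- rep_len(as.numeric(target_mm), 3L)
  if (any(target_mm <= 0)) abort("`target_mm` must be positive.")
  src_mm <- map$resolution_mm
  d <- dim(map$values)
  if (isTRUE(all.equal(src_mm, target_mm))) return(map)
  new_d <- pmax(1L, as.integer(round(d * src_mm / target_mm)))
  idx <- lapply(1:3, function(a) {
    centers <- (seq_len(new_d[a]) - 0.5) * target_mm[a]
    pmin(pmax(ceiling(centers / src_mm[a]), 1L), d[a])
  })
  grid <- as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))
  vals <- array(map$values[grid], new_d)
  msk <- array(map$mask[grid], new_d)
  reho_map(vals, msk, K_policy = map$K_policy, resolution_mm = target_mm)
}

#' Shuffle a ReHo map's defined values
#'
#' Randomization control for the cluster-size analysis: permutes the
#' defined (non-`NA`) values uniformly at random among the defined voxel
#' locations, preserving the value multiset and the mask exactly. A map
#' with planted spatial structure loses its large suprathreshold
#' components (and hence its heavy-tailed cluster-size distribution)
#' under this shuffle.
#'
#' @param map a [reho_map()].
#' @param seed integer seed; the permutation is seed-reproducible.
#' @return a `reho_map` with permuted values.
#' @export
shuffle_map <- function(map, seed) {
  stopifnot(inherits(map, "reho_map"))
  def <- which(!is.na(map$values))
  if (length(def) < 2L) abort("need at least 2 defined voxels to shuffle.")
  perm <- with_preserved_seed(as.integer(seed), sample.int(length(def)))
  map$values[def] <- map$values[def][perm]
  map
}
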