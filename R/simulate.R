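#' Simulation configuration
#'
#' Parameters of one synthetic resting-state acquisition. Defaults mirror
#' the data regime the pipeline targets: 155 frames at TR = 2 s on a 3 mm
#' grid, locally coherent patches whose sizes follow a truncated power
#' law, and a 0.01-0.08 Hz passband for the shared latent signals.
#'
#' @param grid_shape 3 positive integers, voxels per axis.
#' @param n_timepoints number of frames (>= 2).
#' @param tr_seconds repetition time, seconds.
#' @param n_patches number of coherent patches to plant.
#' @param alpha_true target power-law exponent of patch sizes (> 1).
#' @param size_min,size_max patch-size truncation bounds, voxels. The
#'   default floor is one full 3x3x3 ReHo neighbourhood (27 voxels):
#'   a coherent patch smaller than the concordance kernel cannot form a
#'   detectable hot-spot, so planting one would only add unmeasurable
#'   background structure.
#' @param coupling peak fraction of in-patch voxel variance carried by the
#'   patch's shared band-limited latent signal, in \[0, 1\]. The coupling
#'   is graded within each patch: full at one interior peak voxel,
#'   decaying linearly with within-patch geodesic (hop) distance to
#'   `coupling * (1 - coupling_decay)` at the patch's farthest voxel, so
#'   each coherent patch produces a single peaked ReHo hot-spot (a flat
#'   plateau would fragment into arbitrary noise-driven islands under
#'   sparse thresholds).
#' @param coupling_decay fractional coupling drop from patch peak to
#'   edge, in \[0, 1\]; 0 gives spatially uniform coupling.
#' @param coupling_size_exponent exponent of the mild size dependence of
#'   the peak coupling, `peak ~ coupling * (size / 27)^exponent` (capped
#'   at 0.95): larger coherent patches are stronger hubs, as in real
#'   ReHo maps where bigger hot-spots carry higher peaks. 0 disables.
#' @param noise_sd SD of the voxel signals.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @param band passband (Hz) of the latent signals.
#' @param total_patch_volume optional target for the summed patch sizes;
#'   when set, drawn sizes are rescaled so the total is ~constant across
#'   participants (used by [simulate_cohort()] so patch *count* varies
#'   while suprathreshold volume stays comparable).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(grid_shape = c(32, 32, 32), n_timepoints = 155,
                              tr_seconds = 2, n_patches = 25,
                              alpha_true = 2.5, size_min = 27, size_max = 500,
                              coupling = 0.7, coupling_decay = 0.6,
                              coupling_size_exponent = 0.15,
                              noise_sd = 1, seed = 1,
                              band = c(0.01, 0.08),
                              total_patch_volume = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            n_timepoints >= 2, tr_seconds > 0, n_patches >= 0,
            alpha_true > 1, size_min >= 1, size_max >= size_min,
            size_max <= prod(grid_shape),
            coupling >= 0, coupling <= 1,
            coupling_decay >= 0, coupling_decay <= 1,
            coupling_size_exponent >= 0, noise_sd > 0,
            length(band) == 2L, band[1] > 0, band[2] > band[1])
  structure(list(
    grid_shape = grid_shape, n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, n_patches = as.integer(n_patches),
    alpha_true = alpha_true, size_min = as.integer(size_min),
    size_max = as.integer(size_max), coupling = coupling,
    coupling_decay = coupling_decay,
    coupling_size_exponent = coupling_size_exponent,
    noise_sd = noise_sd, seed = as.integer(seed), band = band,
    total_patch_volume = total_patch_volume), class = "simulation_config")
}

#' Sample patch sizes from a truncated power law
#'
#' Inverse-CDF sampling of `P(s) ~ s^(-alpha)` truncated to
#' `[size_min, size_max]`. With `continuous = FALSE` the continuous draws
#' are rounded to integers (clamped to the bounds).
#'
#' @param n number of sizes.
#' @param alpha exponent (> 1).
#' @param size_min,size_max truncation bounds.
#' @param continuous return the raw continuous draws?
#' @return numeric (or integer) vector of length `n`.
#' @export
sample_patch_sizes <- function(n, alpha, size_min, size_max,
                               continuous = FALSE) {
  stopifnot(alpha > 1, size_min > 0, size_max >= size_min)
  u <- runif(n)
  a1 <- 1 - alpha
  s <- (size_min^a1 + u * (size_max^a1 - size_min^a1))^(1 / a1)
  if (continuous) s
  else pmin(pmax(as.integer(round(s)), as.integer(size_min)),
            as.integer(size_max))
}

# --- geometry helpers -------------------------------------------------------

# normalized ellipsoidal radius of every voxel (1 at the brain surface)
norm_radius <- function(dims) {
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - (dims[a] + 1) / 2) /
                                   (0.45 * dims[a]))^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  sqrt(r2)
}

make_brain_mask <- function(dims) norm_radius(dims) <= 1

# Grey matter: the brain minus a deep core, cut by thin sulcus-like slit
# planes so that a surface patch can be split by the anatomical constraint.
make_gm_mask <- function(dims) {
  rho <- norm_radius(dims)
  gm <- rho <= 1 & rho >= 0.35
  slits <- round(dims[1] * c(0.30, 0.62))
  ix <- slot_index_array(dims, 1)
  gm & !(ix %in% slits & rho > 0.55)
}

slot_index_array <- function(dims, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  aperm(array(seq_len(dims[axis]), dims[perm]), order(perm))
}

# linear-index 6-neighbours (within bounds), may contain duplicates
neighbors6 <- function(idx, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  i0 <- idx - 1L
  x <- i0 %% nx; y <- (i0 %/% nx) %% ny; z <- i0 %/% (nx * ny)
  out <- c(
    idx[x > 0] - 1L, idx[x < nx - 1L] + 1L,
    idx[y > 0] - nx, idx[y < ny - 1L] + nx,
    idx[z > 0] - nx * ny, idx[z < nz - 1L] + nx * ny)
  out
}

# linear-index 26-neighbours (within bounds), may contain duplicates
neighbors26 <- function(idx, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  i0 <- idx - 1L
  x <- i0 %% nx; y <- (i0 %/% nx) %% ny; z <- i0 %/% (nx * ny)
  out <- integer(0)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    ok <- x + dx >= 0 & x + dx < nx & y + dy >= 0 & y + dy < ny &
      z + dz >= 0 & z + dz < nz
    out <- c(out, idx[ok] + dx + dy * nx + dz * nx * ny)
  }
  out
}

# set-dilation helpers on linear-index vectors
dilate_set6 <- function(idx, dims, r) {
  out <- idx
  frontier <- idx
  for (i in seq_len(r)) {
    frontier <- setdiff(unique(neighbors6(frontier, dims)), out)
    if (!length(frontier)) break
    out <- c(out, frontier)
  }
  out
}

# Region-growing placement of connected patches (6-connected accretion).
# A 1-voxel 26-connected shell is reserved around every patch so patches
# never touch: the baseline component count equals the requested count,
# and merging is introduced only by the training-effect bridging.
# Returns an integer label volume; errors if a patch cannot be placed.
place_patches <- function(sizes, allowed, dims, n_retry = 25L) {
  lab <- integer(prod(dims))
  occupied <- !as.logical(allowed)
  if (sum(!occupied) < sum(sizes))
    abort("total requested patch volume exceeds the available mask volume.")
  for (p in order(-sizes)) {
    target <- sizes[p]
    placed <- FALSE
    for (try in seq_len(n_retry)) {
      free <- which(!occupied)
      seed_v <- free[sample.int(length(free), 1L)]
      patch <- seed_v
      inpatch <- occupied
      inpatch[seed_v] <- TRUE
      while (length(patch) < target) {
        nb <- unique(neighbors6(patch, dims))
        nb <- nb[!inpatch[nb]]
        if (!length(nb)) break
        take <- min(target - length(patch), length(nb))
        add <- if (take < length(nb)) sample(nb, take) else nb
        inpatch[add] <- TRUE
        patch <- c(patch, add)
      }
      if (length(patch) == target) {
        lab[patch] <- p
        occupied[patch] <- TRUE
        occupied[unique(neighbors26(patch, dims))] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort(sprintf(
        "failed to place a %d-voxel patch after %d retries (mask too full).",
        target, n_retry))
  }
  array(lab, dims)
}

# Merge the spatially closest pairs of patches by drawing a short
# 6-connected bridge (thickened by one voxel) between each pair inside
# `mask`. `fraction` is the fraction of patches that take part in a
# merge: fraction = 1 pairs every patch with its nearest unpaired
# neighbour. This is the training-effect mechanism — close hub pairs
# integrate into one coherent unit; total coupled volume barely changes.
merge_nearest_pairs <- function(lab, mask, fraction) {
  n <- max(lab)
  if (n < 2L || fraction <= 0) return(lab)
  dims <- dim(lab)
  ids <- which(lab > 0)
  coords <- arrayInd(ids, dims)
  cent <- rowsum(coords, lab[ids]) / as.vector(table(lab[ids]))
  n_pairs <- min(floor(min(fraction, 1) * n / 2), n %/% 2)
  if (n_pairs < 1L) return(lab)
  dmat <- as.matrix(stats::dist(cent))
  diag(dmat) <- Inf
  pairs <- list()
  used <- rep(FALSE, n)
  ord <- order(dmat)
  for (k in ord) {
    if (length(pairs) >= n_pairs) break
    i <- (k - 1) %% n + 1
    j <- (k - 1) %/% n + 1
    if (i >= j || used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    pairs[[length(pairs) + 1]] <- c(i, j)
  }
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    path <- bridge_path(lab, mask, a, b, dims)
    if (is.null(path)) next
    # a thick bridge: thin necks depress the concordance field (partial
    # neighbourhoods) and would split the merged hub at high thresholds
    widened <- intersect(dilate_set6(path, dims, 2L), which(mask & lab == 0L))
    lab[unique(c(path, widened))] <- a
    lab[lab == b] <- a
  }
  lab
}

# shortest 6-connected path from patch a to patch b through mask voxels,
# excluding other patches; NULL if none exists
bridge_path <- function(lab, mask, a, b, dims) {
  passable <- (mask & lab == 0L) | lab == b
  parent <- integer(prod(dims))
  frontier <- which(lab == a)
  seen <- logical(prod(dims))
  seen[frontier] <- TRUE
  hit <- NA_integer_
  while (length(frontier) && is.na(hit)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- neighbors6(v, dims)
      nb <- nb[passable[nb] & !seen[nb]]
      if (!length(nb)) next
      seen[nb] <- TRUE
      parent[nb] <- v
      if (any(lab[nb] == b)) {
        hit <- nb[lab[nb] == b][1]
        break
      }
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  if (is.na(hit)) return(NULL)
  path <- integer(0)
  v <- parent[hit]
  while (v != 0L && lab[v] != a) {
    if (lab[v] == 0L) path <- c(path, v)
    v <- parent[v]
  }
  path
}

# band-limited unit-variance latent signals, one per column
band_limited_latents <- function(nt, k, tr, band) {
  L <- fft_bandpass(matrix(rnorm(nt * k), nt, k), tr, band[1], band[2])
  sw <- apply(L, 2, sd)
  sw[sw == 0] <- 1
  sweep(L, 2, sw, `/`)
}

simulate_motion <- function(nt, scale = 1) {
  steps <- cbind(matrix(rnorm(nt * 3, 0, 0.02), nt, 3),
                 matrix(rnorm(nt * 3, 0, 4e-4), nt, 3)) * scale
  m <- apply(steps, 2, cumsum)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

# --- participant-level simulation -------------------------------------------

# Per-voxel coupling: peak at one interior voxel per patch, decaying
# linearly with geodesic (within-patch, 6-connected hop) distance to
# peak * (1 - decay) at the patch's farthest voxel. Geodesic level sets
# are connected whatever the patch's shape, so each coherent patch
# produces exactly one peaked ReHo core.
graded_coupling <- function(labels, ids, peak, decay, size_exponent = 0) {
  dims <- dim(labels)
  labv <- labels[ids]
  if (decay == 0 && size_exponent == 0) return(rep(peak, length(ids)))
  coords <- arrayInd(ids, dims)
  cvec <- numeric(length(ids))
  for (k in unique(labv)) {
    sel <- which(labv == k)
    peak_k <- min(0.95, peak * (length(sel) / 27)^size_exponent)
    if (decay == 0) {
      cvec[sel] <- peak_k
      next
    }
    xyz <- coords[sel, , drop = FALSE]
    ctr <- colMeans(xyz)
    d2 <- colSums((t(xyz) - ctr)^2)
    seed_v <- ids[sel[order(d2, ids[sel])[1]]]   # deterministic peak voxel
    # BFS hop distance within the patch
    dist <- rep(NA_integer_, length(sel))
    dist[match(seed_v, ids[sel])] <- 0L
    frontier <- seed_v
    level <- 0L
    while (length(frontier)) {
      level <- level + 1L
      nb <- unique(neighbors6(frontier, dims))
      nb <- nb[labels[nb] == k]
      nb_local <- match(nb, ids[sel])
      nb_local <- nb_local[!is.na(nb_local) & is.na(dist[nb_local])]
      if (!length(nb_local)) break
      dist[nb_local] <- level
      frontier <- ids[sel][nb_local]
    }
    dist[is.na(dist)] <- max(dist, na.rm = TRUE) + 1L  # unreachable guard
    dmax <- max(dist)
    cvec[sel] <- if (dmax == 0) peak_k
                 else peak_k * (1 - decay * dist / dmax)
  }
  cvec
}

sim_images <- function(config, patch_labels, noise_seed) {
  dims <- config$grid_shape
  nt <- config$n_timepoints
  with_preserved_seed(noise_seed, {
    dat <- matrix(rnorm(prod(dims) * nt, 0, config$noise_sd),
                  nrow = prod(dims))
    ids <- which(patch_labels > 0)
    if (length(ids) && config$coupling > 0) {
      n_pat <- max(patch_labels)
      lat <- band_limited_latents(nt, n_pat, config$tr_seconds, config$band)
      cvec <- graded_coupling(patch_labels, ids, config$coupling,
                              config$coupling_decay,
                              config$coupling_size_exponent)
      dat[ids, ] <- config$noise_sd *
        (sqrt(cvec) * t(lat)[patch_labels[ids], , drop = FALSE] +
           sqrt(1 - cvec) * matrix(rnorm(length(ids) * nt), length(ids)))
    }
    bold_series(array(dat, c(dims, nt)), voxel_size_mm = c(3, 3, 3),
                tr_seconds = config$tr_seconds, space_tag = "synthetic")
  })
}

#' Simulate one synthetic participant
#'
#' Generates a 4D BOLD-like volume containing `n_patches` contiguous
#' patches of locally coherent signal (each patch shares a band-limited
#' latent signal carrying `coupling` of the in-patch variance), an
#' ellipsoidal brain mask, a shell-like grey-matter mask with sulcus
#' slits, a plausible rigid-body motion trace, and the ground-truth patch
#' labels. Patch sizes are drawn from the truncated power law
#' `P(s) ~ s^(-alpha_true)` on `[size_min, size_max]`.
#'
#' @param config a [simulation_config()].
#' @param merge_fraction real in \[0, 1\]; merges this fraction of
#'   patches with their nearest neighbour (short bridges drawn between
#'   the closest pairs) before synthesis — the mechanism used to emulate
#'   a training-related integration increase.
#' @return list with elements `bold` ([bold_series()]), `brain_mask`,
#'   `gm_mask` (3D logical), `motion` (t x 6 matrix), `patches` (list:
#'   `labels` 3D integer array, `sizes` tibble with merged component
#'   sizes, `n_patches`, `mean_size`).
#' @export
simulate_participant <- function(config, merge_fraction = 0) {
  stopifnot(inherits(config, "simulation_config"))
  dims <- config$grid_shape
  brain <- make_brain_mask(dims)
  gm <- make_gm_mask(dims)
  layout <- with_preserved_seed(config$seed, {
    sizes <- draw_scaled_sizes(config)
    # patches grow inside grey matter: local-FC hubs are cortical, and a
    # coherent core planted in the deep non-GM interior would be an
    # artefact the anatomical constraint immediately destroys
    lab <- if (length(sizes)) place_patches(sizes, gm, dims)
           else array(0L, dims)
    lab
  })
  if (merge_fraction > 0)
    layout <- with_preserved_seed(config$seed + 17L,
      merge_nearest_pairs(layout, brain, merge_fraction))
  gt <- patch_ground_truth(layout)
  layout <- gt$labels   # merged components become the coherent units
  bold <- sim_images(config, layout, noise_seed = config$seed + 1000003L)
  motion <- with_preserved_seed(config$seed + 2000003L,
                                simulate_motion(config$n_timepoints))
  list(bold = bold, brain_mask = brain, gm_mask = gm, motion = motion,
       patches = gt)
}

draw_scaled_sizes <- function(config) {
  if (config$n_patches == 0L) return(integer())
  sizes <- sample_patch_sizes(config$n_patches, config$alpha_true,
                              config$size_min, config$size_max)
  if (!is.null(config$total_patch_volume)) {
    sizes <- pmax(config$size_min,
                  as.integer(round(sizes * config$total_patch_volume /
                                     sum(sizes))))
  }
  sizes
}

# Merged-component ground truth of a (possibly dilated) patch label
# volume. Patches that touch after dilation count as one coherent unit
# (they share one latent signal downstream), so the returned `labels`
# re-partition the patch voxels by connected component.
patch_ground_truth <- function(labels) {
  comp <- label_components(labels > 0L, connectivity = 26L)
  list(labels = comp$labels,
       sizes = comp$clusters[c("id", "size_voxels")],
       n_patches = comp$n_clusters,
       mean_size = comp$mean_size)
}
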