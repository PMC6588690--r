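# Independent oracles used across the suite. These deliberately use naive,
# loop-based formulations so they share no code path with the package.

# Kendall's W by direct summation of the concordance formula.
naive_kendalls_w <- function(series) {
  K <- nrow(series)
  N <- ncol(series)
  ranks <- matrix(0, K, N)
  for (k in seq_len(K)) ranks[k, ] <- rank(series[k, ])
  Ri <- numeric(N)
  for (i in seq_len(N)) {
    for (k in seq_len(K)) Ri[i] <- Ri[i] + ranks[k, i]
  }
  Rbar <- sum(Ri) / N
  num <- 0
  for (i in seq_len(N)) num <- num + Ri[i]^2
  (num - N * Rbar^2) / ((1 / 12) * K^2 * (N^3 - N))
}

# Per-voxel brute-force ReHo: gather the in-mask 3x3x3 neighbourhood and
# apply naive_kendalls_w.
naive_reho_map <- function(data4d, mask, min_neighbors = 27L) {
  d <- dim(data4d)
  out <- array(NA_real_, d[1:3])
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z]) next
    xs <- max(1, x - 1):min(d[1], x + 1)
    ys <- max(1, y - 1):min(d[2], y + 1)
    zs <- max(1, z - 1):min(d[3], z + 1)
    nb <- list()
    for (zz in zs) for (yy in ys) for (xx in xs)
      if (mask[xx, yy, zz]) nb[[length(nb) + 1]] <- data4d[xx, yy, zz, ]
    if (length(nb) < min_neighbors || length(nb) < 2) next
    out[x, y, z] <- naive_kendalls_w(do.call(rbind, nb))
  }
  out
}

# Connected components by breadth-first flood fill over an explicit
# neighbour offset table.
flood_fill_labels <- function(binary, connectivity) {
  d <- dim(binary)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, d)
  nxt <- 0L
  for (i in which(binary)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      v0 <- v - 1L
      x <- v0 %% d[1] + 1L
      y <- (v0 %/% d[1]) %% d[2] + 1L
      z <- v0 %/% (d[1] * d[2]) + 1L
      for (j in seq_len(nrow(offs))) {
        xx <- x + offs$dx[j]; yy <- y + offs$dy[j]; zz <- z + offs$dz[j]
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
            zz < 1 || zz > d[3]) next
        w <- xx + d[1] * (yy - 1L) + d[1] * d[2] * (zz - 1L)
        if (binary[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# membership partition as a canonical set-of-sets signature
component_signature <- function(lab) {
  parts <- split(which(lab > 0), lab[lab > 0])
  sig <- sort(vapply(parts, function(v) paste(sort(v), collapse = ","), ""))
  unname(sig)
}

# Benjamini-Hochberg step-up, written from the definition.
bh_step_up <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, (m / i) * p[ord[i]])
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# Inverse-CDF sampler for the truncated power law P(s) ~ s^(-alpha).
truncated_powerlaw_oracle <- function(n, alpha, s_min, s_max) {
  u <- runif(n)
  a1 <- 1 - alpha
  (s_min^a1 + u * (s_max^a1 - s_min^a1))^(1 / a1)
}

# OLS residuals through the normal equations.
normal_equations_resid <- function(y, X) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  as.numeric(y - X1 %*% beta)
}
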