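test_that("logarithmic binning reproduces the hand-tallied example", {
  d <- log_bin(1:8, base = 2)
  expect_equal(d$bin_lo, c(1, 2, 4, 8))
  expect_equal(d$count, c(1L, 2L, 4L, 1L))
  expect_equal(d$density, c(0.125, 0.125, 0.125, 0.015625))
  expect_error(log_bin(numeric(0)), "empty")
  expect_error(log_bin(c(1, -2)), "positive")
})

test_that("binned densities always integrate to one", {
  withr::with_seed(6, {
    for (i in 1:10) {
      sizes <- sample(1:5000, sample(5:500, 1), replace = TRUE)
      d <- log_bin(sizes, base = sample(c(1.5, 2, 3), 1))
      expect_equal(sum(d$density * (d$bin_hi - d$bin_lo)), 1,
                   tolerance = 1e-9)
    }
    one <- log_bin(rep(7, 50))
    expect_equal(sum(one$count > 0), 1L)
    expect_equal(sum(one$density * (one$bin_hi - one$bin_lo)), 1,
                 tolerance = 1e-9)
  })
})

test_that("exact analytic power-law densities are fit perfectly", {
  centers <- 2^(5:14)
  dist <- tibble::tibble(bin_center = centers,
                         density = 0.37 * centers^(-2))
  fit <- fit_powerlaw(dist, s_min_fit = 100)
  expect_equal(fit$alpha, 2.0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-10)
  expect_lt(fit$stderr_alpha, 1e-10)
})

test_that("a short tail raises an explicit error", {
  dist <- tibble::tibble(bin_center = c(10, 150, 300),
                         density = c(0.1, 0.01, 0.001))
  expect_error(fit_powerlaw(dist, s_min_fit = 100), "tail too short")
})

test_that("sampled truncated power laws are recovered within the stated band", {
  for (case in list(list(alpha = 2.0, seed = 51), list(alpha = 2.5, seed = 52),
                    list(alpha = 3.0, seed = 53))) {
    sizes <- withr::with_seed(case$seed,
      sample_patch_sizes(20000, case$alpha, 100, 1e4, continuous = TRUE))
    fit <- fit_powerlaw(log_bin(sizes), s_min_fit = 100)
    expect_lt(abs(fit$alpha - case$alpha), 0.15)
    # MLE cross-check agrees with the binned regression
    expect_lt(abs(fit_powerlaw_mle(sizes, 100) - case$alpha), 0.1)
  }
})

test_that("halving the bin base leaves the fitted exponent within 2 SE", {
  sizes <- withr::with_seed(60,
    sample_patch_sizes(20000, 2.5, 100, 1e4, continuous = TRUE))
  f2 <- fit_powerlaw(log_bin(sizes, base = 2))
  f14 <- fit_powerlaw(log_bin(sizes, base = sqrt(2)))
  expect_lt(abs(f2$alpha - f14$alpha),
            2 * (f2$stderr_alpha + f14$stderr_alpha))
})

test_that("the size sampler matches an inverse-CDF oracle distributionally", {
  mine <- withr::with_seed(71,
    sample_patch_sizes(20000, 2.5, 1, 1e4, continuous = TRUE))
  oracle <- withr::with_seed(72,
    truncated_powerlaw_oracle(20000, 2.5, 1, 1e4))
  ks <- suppressWarnings(stats::ks.test(mine, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("exponent/count/size relations are reported with signs and guards", {
  withr::with_seed(80, {
    n_cl <- round(runif(30, 20, 200))
    total <- 2000
    mean_size <- total / n_cl
    alpha <- 1.5 + 0.004 * n_cl + rnorm(30, 0, 0.05)
    rel <- exponent_metric_relations(
      tibble::tibble(alpha = alpha, n_clusters = n_cl, mean_size = mean_size))
    get <- function(a, b) rel[rel$var1 == a & rel$var2 == b, ]
    expect_lt(get("n_clusters", "mean_size")$estimate, 0)
    expect_gt(get("alpha", "n_clusters")$estimate, 0)
    # zero-variance metric flagged, not reported as 0
    rel0 <- exponent_metric_relations(
      tibble::tibble(alpha = alpha, n_clusters = n_cl, mean_size = 5))
    expect_false(get("n_clusters", "mean_size")$defined &&
                   is.na(get("n_clusters", "mean_size")$estimate))
    row0 <- rel0[rel0$var1 == "n_clusters" & rel0$var2 == "mean_size", ]
    expect_false(row0$defined)
    expect_true(is.na(row0$estimate))
    expect_error(exponent_metric_relations(
      tibble::tibble(alpha = 1:2, n_clusters = 1:2, mean_size = 1:2)),
      ">= 4")
  })
})

test_that("shuffling a structured map destroys its large components", {
  # a map with one compact high-ReHo blob: after shuffling, the top-10%
  # set breaks into scattered fragments
  dims <- c(20, 20, 20)
  vals <- withr::with_seed(90, array(runif(prod(dims), 0, 0.2), dims))
  blob <- array(FALSE, dims); blob[8:15, 8:15, 8:15] <- TRUE  # 512 voxels
  vals[blob] <- withr::with_seed(91, runif(sum(blob), 0.6, 0.9))
  map <- map_from_values(vals)
  structured <- label_components(threshold_top_fraction(map, 0.10), 26)
  shuffled <- label_components(
    threshold_top_fraction(shuffle_map(map, seed = 1), 0.10), 26)
  expect_gt(max(structured$clusters$size_voxels),
            3 * max(shuffled$clusters$size_voxels))
})
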