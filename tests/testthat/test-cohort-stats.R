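test_that("confound residualization is exact, orthogonal, and idempotent", {
  withr::with_seed(101, {
    n <- 40
    conf <- cbind(education = round(runif(n, 6, 18)),
                  gender = rbinom(n, 1, 0.5),
                  mean_fd = runif(n, 0.05, 0.3))
    # values exactly linear in education -> constant at the grand mean
    v1 <- 3 * conf[, 1] - 2
    r1 <- residualize_confounds(v1, conf)
    expect_equal(r1, rep(mean(v1), n), tolerance = 1e-10)
    # random values match the normal-equations oracle
    y <- rnorm(n)
    r <- residualize_confounds(y, conf)
    expect_equal(r, normal_equations_resid(y, conf) + mean(y),
                 tolerance = 1e-10)
    for (j in 1:3)
      expect_lt(abs(sum((r - mean(r)) * conf[, j])), 1e-8)
    # idempotence
    expect_equal(residualize_confounds(r, conf), r, tolerance = 1e-10)
    # values orthogonal to centred confounds pass through
    cc <- scale(conf, scale = FALSE)
    y2 <- rnorm(n)
    y2 <- y2 - cc %*% solve(crossprod(cc), crossprod(cc, y2))
    expect_equal(residualize_confounds(as.numeric(y2), conf),
                 as.numeric(y2), tolerance = 1e-10)
    expect_error(residualize_confounds(y, cbind(conf, conf[, 1])), "rank")
  })
})

test_that("group contrasts return null results on null data and errors on bad designs", {
  tb <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:10), 2),
    group = rep(rep(c("a", "b"), each = 5), 2),
    timepoint = rep(c("baseline", "follow-up"), each = 10),
    m = c(1:10, 1:10))  # identical at both timepoints
  two <- group_contrast(dplyr::filter(tb, timepoint == "baseline"),
                        "m", "two_sample_t")
  # identical groups -> t = 0, p = 1
  tb2 <- tb; tb2$m <- rep(rep(1:5, 2), 2)
  t0 <- group_contrast(dplyr::filter(tb2, timepoint == "baseline"),
                       "m", "two_sample_t")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # paired differences (+1, -1) -> t = 0
  tb3 <- tibble::tibble(
    participant_id = rep(c("P1", "P2"), 2),
    group = "a",
    timepoint = rep(c("baseline", "follow-up"), each = 2),
    m = c(0, 0, 1, -1))
  p0 <- group_contrast(tb3, "m", "paired_t")
  expect_equal(p0$statistic, 0)
  # zero-variance paired differences flagged undefined
  z <- group_contrast(tb, "m", "paired_t")
  expect_false(z$defined)
  expect_error(group_contrast(
    tibble::tibble(participant_id = "P1", group = "a",
                   timepoint = "baseline", m = 1), "m", "two_sample_t"),
    "n >= 2")
})

test_that("two-sample t matches the pooled-variance textbook formula", {
  withr::with_seed(17, {
    x <- rnorm(15, 0.3); y <- rnorm(15)
    tb <- tibble::tibble(
      participant_id = sprintf("P%02d", 1:30),
      group = rep(c("a", "b"), each = 15),
      timepoint = "baseline", m = c(x, y))
    got <- group_contrast(tb, "m", "two_sample_t")
    sp2 <- ((15 - 1) * var(x) + (15 - 1) * var(y)) / 28
    t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 15))
    expect_equal(abs(got$statistic), abs(t_oracle), tolerance = 1e-10)
    expect_equal(as.numeric(got$df), 28)
    expect_equal(got$p_value, 2 * stats::pt(-abs(t_oracle), 28),
                 tolerance = 1e-10)
  })
})

test_that("correlations hit exact anchors and the rank-transform oracle", {
  x <- 1:10
  expect_equal(correlate(x, x, "pearson")$estimate, 1)
  expect_equal(correlate(x, x, "spearman")$estimate, 1)
  expect_equal(correlate(x, -2 * x + 3, "pearson")$estimate, -1)
  withr::with_seed(23, {
    a <- rnorm(48); b <- rnorm(48)
    got <- correlate(a, b, "spearman")$estimate
    expect_equal(got, cor(rank(a), rank(b)), tolerance = 1e-12)
  })
  z <- correlate(rep(1, 10), rnorm(10))
  expect_false(z$defined)
  expect_error(correlate(1:3, 1:3), "n >= 4")
})

test_that("BH adjustment reproduces the step-up oracle and its anchors", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  withr::with_seed(29, {
    for (i in 1:10) {
      p <- runif(sample(3:100, 1))
      adj <- fdr_bh(p)
      expect_equal(adj, bh_step_up(p))
      expect_true(all(adj >= p))
      ord <- order(p)
      expect_true(all(diff(adj[ord]) >= -1e-15))
    }
  })
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("KS normality routing separates normal from exponential samples", {
  withr::with_seed(33, {
    expect_gt(ks_normality(rnorm(500))$p_value, 0.05)
    expect_lt(ks_normality(rexp(500))$p_value, 0.01)
  })
  expect_false(ks_normality(rep(2, 10))$defined)
  expect_error(ks_normality(1:3), "n >= 5")
})

test_that("mixed Group x Threshold ANOVA detects planted effects and flags gaps", {
  make_tbl <- function(group_shift = 0, slope = 0, seed = 1, n = 20) {
    withr::with_seed(seed, {
      ths <- c(0.05, 0.10, 0.15, 0.20)
      g <- rep(c("t", "c"), each = n)
      purrr::map_dfr(seq_along(g), function(i) {
        base <- rnorm(4)
        fup <- base + rnorm(4, 0, 0.3) +
          (g[i] == "t") * (group_shift + slope * seq_along(ths))
        tibble::tibble(
          participant_id = sprintf("P%02d", i), group = g[i],
          threshold = rep(ths, 2),
          timepoint = rep(c("baseline", "follow-up"), each = 4),
          m = c(base, fup))
      })
    })
  }
  shifted <- rm_anova_group_by_threshold(make_tbl(group_shift = 1), "m")
  expect_lt(shifted$p_value[shifted$method == "rm_anova_group_main"], 0.05)
  inter <- rm_anova_group_by_threshold(make_tbl(slope = 0.5), "m")
  expect_lt(inter$p_value[inter$method == "rm_anova_interaction"], 0.05)
  broken <- make_tbl()[-1, ]   # P01 lost a threshold cell
  expect_error(rm_anova_group_by_threshold(broken, "m"), "P01")
})
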