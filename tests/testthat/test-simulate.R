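test_that("config validation enforces the documented invariants", {
  expect_error(simulation_config(size_min = 50, size_max = 10))
  expect_error(simulation_config(coupling = 1.5))
  expect_error(simulation_config(alpha_true = 1))
  expect_error(simulation_config(grid_shape = c(4, 4), size_max = 8))
  expect_error(cohort_design(n_per_group = 1), "n_per_group")
})

test_that("identical config and seed give bit-identical participants", {
  cfg <- tiny_config(seed = 33)
  a <- simulate_participant(cfg)
  b <- simulate_participant(cfg)
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(a$motion, b$motion)
  expect_identical(a$patches$labels, b$patches$labels)
  c2 <- simulate_participant(tiny_config(seed = 34))
  expect_false(identical(a$bold$data, c2$bold$data))
})

test_that("patches live inside the brain mask and gm is a subset of brain", {
  p <- simulate_participant(tiny_config(seed = 35))
  expect_true(all(p$brain_mask[p$patches$labels > 0]))
  expect_true(all(p$brain_mask[p$gm_mask]))
  # gm has gaps (it can split clusters)
  expect_lt(sum(p$gm_mask), sum(p$brain_mask))
})

test_that("placement fails loudly when patches cannot fit", {
  cfg <- simulation_config(grid_shape = c(8, 8, 8), n_timepoints = 10,
                           n_patches = 40, size_min = 60, size_max = 80,
                           seed = 1)
  expect_error(simulate_participant(cfg), "volume|place")
})

test_that("zero coupling leaves in-patch series uncorrelated; full coupling gives W = 1", {
  cfg0 <- tiny_config(seed = 36, coupling = 0, n_timepoints = 150,
                      n_patches = 2, size_min = 60, size_max = 80)
  p0 <- simulate_participant(cfg0)
  ids <- which(p0$patches$labels == 1L)
  mat <- matrix(p0$bold$data, ncol = 150)[ids[1:20], ]
  cors <- cor(t(mat))
  expect_lt(abs(mean(cors[upper.tri(cors)])), 0.05)

  # uniform full coupling: identical in-patch series, exact concordance
  cfg1 <- tiny_config(seed = 37, coupling = 1, coupling_decay = 0,
                      coupling_size_exponent = 0,
                      n_patches = 1, size_min = 150, size_max = 150)
  p1 <- simulate_participant(cfg1)
  map <- compute_reho(p1$bold, p1$brain_mask)
  interior <- which(!is.na(map$values) & p1$patches$labels > 0, arr.ind = TRUE)
  # fully-interior patch voxels: all 27 neighbours inside the patch
  w_in <- vapply(seq_len(nrow(interior)), function(i) {
    v <- interior[i, ]
    nb <- p1$patches$labels[(v[1]-1):(v[1]+1), (v[2]-1):(v[2]+1),
                            (v[3]-1):(v[3]+1)]
    if (all(nb == 1L)) map$values[v[1], v[2], v[3]] else NA_real_
  }, 0)
  w_in <- w_in[!is.na(w_in)]
  expect_gt(length(w_in), 0)
  expect_equal(w_in, rep(1, length(w_in)), tolerance = 1e-12)
})

test_that("patch sizes follow the truncated power law (KS vs inverse-CDF oracle)", {
  mine <- withr::with_seed(1,
    sample_patch_sizes(20000, 2.5, 8, 500, continuous = TRUE))
  oracle <- withr::with_seed(2,
    truncated_powerlaw_oracle(20000, 2.5, 8, 500))
  expect_gt(suppressWarnings(stats::ks.test(mine, oracle))$p.value, 0.01)
  ints <- withr::with_seed(3, sample_patch_sizes(1000, 2.5, 8, 500))
  expect_true(all(ints >= 8 & ints <= 500))
  expect_true(is.integer(ints))
})

test_that("cohort structure: both timepoints, controls untreated, attendance rules", {
  cfg <- tiny_config(seed = 40)
  des <- tiny_design(n_per_group = 4, fraction_incomplete = 0.5,
                     groups = c("multi-domain", "single-domain", "control"))
  sim <- simulate_cohort(des, cfg)
  co <- sim$cohort
  expect_equal(nrow(co), 4 * 3 * 2)
  expect_true(all(table(co$participant_id) == 2))
  ctrl <- co[grepl("control", co$group), ]
  expect_true(all(ctrl$merge_fraction == 0))
  expect_true(all(is.na(ctrl$attendance)))
  trn <- co[!grepl("control", co$group), ]
  expect_true(all(!is.na(trn$attendance)))
  expect_identical(trn$completer, trn$attendance > 19)
  # static covariates identical across timepoints
  for (colname in c("age", "gender", "education", "attendance")) {
    spread <- tapply(co[[colname]], co$participant_id,
                     function(v) length(unique(v)))
    expect_true(all(spread == 1))
  }
})

test_that("null training effect leaves ground truth unchanged; positive effect integrates", {
  cfg <- tiny_config(seed = 41)
  null_sim <- simulate_cohort(tiny_design(training_effect = 0), cfg)
  d <- null_sim$cohort |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(dn = diff(gt_n_patches), ds = diff(gt_mean_size))
  expect_true(all(d$dn == 0))
  expect_true(all(d$ds == 0))

  eff <- simulate_cohort(tiny_design(training_effect = 1), cfg)
  comp <- eff$cohort[eff$cohort$completer, ]
  wide <- tidyr::pivot_wider(comp[c("participant_id", "timepoint",
                                    "gt_mean_size", "gt_n_patches")],
                             names_from = timepoint,
                             values_from = c(gt_mean_size, gt_n_patches))
  expect_true(all(wide$`gt_mean_size_follow-up` >
                    wide$`gt_mean_size_baseline`))
  expect_true(all(wide$`gt_n_patches_follow-up` <=
                    wide$`gt_n_patches_baseline`))
})

test_that("education couples negatively to the ground-truth patch count", {
  cfg <- tiny_config(seed = 7)
  des <- tiny_design(n_per_group = 30, groups = c("multi-domain", "control"),
                     education_slope = -0.04)
  sim <- simulate_cohort(des, cfg)
  base <- sim$cohort[sim$cohort$timepoint == "baseline", ]
  r <- cor(base$education, base$gt_n_patches)
  expect_lt(r, 0)
  expect_gt(abs(r), 0.2)
})

test_that("rebuilt bundles are identical to materialized ones", {
  cfg <- tiny_config(seed = 44)
  des <- tiny_design(n_per_group = 2)
  sim <- simulate_cohort(des, cfg, materialize = TRUE)
  again <- cohort_bundle(sim, 3)
  expect_identical(again$bold$data, sim$bundles[[3]]$bold$data)
  expect_identical(again$motion, sim$bundles[[3]]$motion)
  expect_identical(again$patches$labels, sim$bundles[[3]]$patches$labels)
})
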