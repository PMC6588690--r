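#' Preprocess a BOLD series the standard way
#'
#' Fixed order: drop initial frames, detrend + band-pass, nuisance
#' regression on the (identically trimmed) six motion parameters. No
#' spatial operation is applied anywhere in preprocessing — spatial
#' smoothing is deliberately absent because it inflates local coherence.
#'
#' @param bold a [bold_series()].
#' @param motion t x 6 motion matrix aligned with the *untrimmed* series.
#' @param n_drop initial frames to discard (default 4).
#' @param low_hz,high_hz passband (default 0.01-0.08 Hz).
#' @param regress_motion regress the motion columns out?
#' @param mask optional 3D logical array restricting the voxel-wise work
#'   (see [detrend_bandpass()]).
#' @return list: `bold` (preprocessed), `motion` (trimmed), `fd`
#'   (framewise displacement of the trimmed motion), `mean_fd`.
#' @export
preprocess_bold <- function(bold, motion, n_drop = 4L,
                            low_hz = 0.01, high_hz = 0.08,
                            regress_motion = TRUE, mask = NULL) {
  stopifnot(inherits(bold, "bold_series"))
  motion <- as.matrix(motion)
  if (nrow(motion) != n_frames(bold))
    abort("motion rows must match the untrimmed frame count.")
  bold <- drop_initial_frames(bold, n_drop)
  motion <- motion[(n_drop + 1L):nrow(motion), , drop = FALSE]
  bold <- detrend_bandpass(bold, low_hz, high_hz, mask = mask)
  if (regress_motion) bold <- regress_nuisance(bold, motion, mask = mask)
  fd <- compute_fd(motion)
  list(bold = bold, motion = motion, fd = fd, mean_fd = mean(fd))
}

#' Per-participant HRC metrics across thresholds
#'
#' Runs one image bundle through preprocessing, ReHo, and HRC extraction
#' at each threshold, returning one row per threshold.
#'
#' @param bundle an image bundle (fields `bold`, `brain_mask`, `gm_mask`,
#'   `motion`), e.g. from [simulate_participant()] or [cohort_bundle()].
#' @param thresholds top-fraction thresholds (default 5/10/15/20%).
#' @param gm_constraint apply the grey-matter constraint?
#' @param connectivity cluster connectivity (6/18/26).
#' @param min_neighbors ReHo edge policy (see [compute_reho()]).
#' @param n_drop,low_hz,high_hz preprocessing settings.
#' @param keep_sizes also return the per-cluster size vectors (for
#'   distribution fitting)?
#' @return tibble: `threshold`, `n_clusters`, `mean_size`,
#'   `total_voxels`, `mean_fd`, and (if `keep_sizes`) a list column
#'   `sizes`.
#' @export
participant_metrics <- function(bundle, thresholds = c(0.05, 0.10, 0.15, 0.20),
                                gm_constraint = TRUE, connectivity = 26L,
                                min_neighbors = 27L, n_drop = 4L,
                                low_hz = 0.01, high_hz = 0.08,
                                keep_sizes = FALSE) {
  pre <- preprocess_bold(bundle$bold, bundle$motion, n_drop = n_drop,
                         low_hz = low_hz, high_hz = high_hz,
                         mask = bundle$brain_mask)
  map <- compute_reho(pre$bold, bundle$brain_mask,
                      min_neighbors = min_neighbors)
  gm <- if (gm_constraint) bundle$gm_mask else NULL
  purrr::map_dfr(thresholds, function(th) {
    hs <- extract_hrcs(map, th, gm_mask = gm, connectivity = connectivity)
    row <- tibble::tibble(threshold = th, n_clusters = hs$n_clusters,
                          mean_size = hs$mean_size,
                          total_voxels = hs$total_voxels,
                          mean_fd = pre$mean_fd)
    if (keep_sizes) row$sizes <- list(hs$clusters$size_voxels)
    row
  })
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a cohort, pushes every participant x timepoint through
#' preprocessing, ReHo and HRC extraction, and runs the longitudinal
#' statistics preset. All randomness derives from `config$seed`; two runs
#' with the same configuration produce byte-identical output tables.
#'
#' @param design a [cohort_design()].
#' @param config a [simulation_config()].
#' @param thresholds extraction thresholds.
#' @param gm_constraint,connectivity,min_neighbors see
#'   [participant_metrics()].
#' @param out_dir if non-`NULL`, writes `cohort.tsv`, `metrics.tsv`,
#'   `stats.tsv` and `manifest.json` there.
#' @param residualize_contrasts residualize education/gender/FD out of the
#'   difference scores before between-group contrasts?
#' @return list: `cohort`, `metrics` (long tibble), `stats` (tidy test
#'   results), `manifest`.
#' @export
run_pipeline <- function(design, config,
                         thresholds = c(0.05, 0.10, 0.15, 0.20),
                         gm_constraint = TRUE, connectivity = 26L,
                         min_neighbors = 27L, out_dir = NULL,
                         residualize_contrasts = TRUE) {
  stopifnot(all(thresholds > 0 & thresholds < 1),
            !is.unsorted(thresholds))
  sim <- simulate_cohort(design, config, materialize = FALSE)
  cohort <- sim$cohort
  metrics <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    bundle <- cohort_bundle(sim, i)
    metrics[[i]] <- participant_metrics(
      bundle, thresholds = thresholds, gm_constraint = gm_constraint,
      connectivity = connectivity, min_neighbors = min_neighbors) |>
      dplyr::mutate(participant_id = cohort$participant_id[i],
                    timepoint = cohort$timepoint[i], .before = 1)
  }
  metrics <- dplyr::bind_rows(metrics)
  stats_tbl <- cohort_stats_preset(cohort, metrics, thresholds,
                                   residualize = residualize_contrasts)
  manifest <- list(
    seed = config$seed,
    grid_shape = config$grid_shape,
    n_timepoints = config$n_timepoints,
    thresholds = thresholds,
    gm_constraint = gm_constraint,
    connectivity = connectivity,
    min_neighbors = min_neighbors,
    n_participants = length(unique(cohort$participant_id)),
    package_version = as.character(utils::packageVersion("rehohub")))
  out <- list(cohort = cohort, metrics = metrics, stats = stats_tbl,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(cohort, file.path(out_dir, "cohort.tsv"))
    readr::write_tsv(metrics, file.path(out_dir, "metrics.tsv"))
    readr::write_tsv(stats_tbl, file.path(out_dir, "stats.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Longitudinal statistics preset
#'
#' The standard battery on HRC count and mean size: per threshold,
#' within-group paired t-tests (completers; controls), a
#' completer-vs-control two-sample t on the before-after differences
#' (optionally residualized on education, gender and baseline mean FD),
#' the mixed Group x Threshold ANOVA per metric, Spearman correlations of
#' education with the baseline metrics at the 10% threshold, and BH-FDR
#' within each test family.
#'
#' @param cohort cohort tibble (from [simulate_cohort()]).
#' @param metrics long metrics tibble (from [participant_metrics()] rows).
#' @param thresholds thresholds present in `metrics`.
#' @param residualize residualize confounds out of difference scores
#'   before the between-group contrasts?
#' @return tidy tibble of test results with columns `family`, `contrast`,
#'   `metric`, `threshold`, plus the `new_test_result` fields and
#'   `adjusted_p` (BH within family).
#' @export
cohort_stats_preset <- function(cohort, metrics, thresholds,
                                residualize = TRUE) {
  base_cov <- cohort |>
    dplyr::filter(.data$timepoint == "baseline") |>
    dplyr::select("participant_id", "group", "age", "gender",
                  "education", "completer")
  long <- metrics |>
    dplyr::left_join(base_cov, by = "participant_id")
  res <- list()
  for (metric in c("n_clusters", "mean_size")) {
    for (th in thresholds) {
      sub <- long |> dplyr::filter(.data$threshold == th)
      cmp <- sub |> dplyr::filter(.data$completer)
      ctl <- sub |> dplyr::filter(is_control_group(.data$group))
      res[[length(res) + 1]] <- group_contrast(cmp, metric, "paired_t") |>
        dplyr::mutate(family = "within_group", contrast = "completers",
                      metric = metric, threshold = th)
      res[[length(res) + 1]] <- group_contrast(ctl, metric, "paired_t") |>
        dplyr::mutate(family = "within_group", contrast = "controls",
                      metric = metric, threshold = th)
      res[[length(res) + 1]] <-
        did_contrast(sub, cohort, metric, residualize) |>
        dplyr::mutate(family = "between_group",
                      contrast = "completers_vs_controls",
                      metric = metric, threshold = th)
    }
    rm_in <- long |>
      dplyr::filter(.data$completer | is_control_group(.data$group)) |>
      dplyr::mutate(group = ifelse(.data$completer, "completer", "control"))
    res[[length(res) + 1]] <-
      rm_anova_group_by_threshold(rm_in, metric, thresholds) |>
      dplyr::mutate(family = "rm_anova", contrast = "completers_vs_controls",
                    metric = metric, threshold = NA_real_)
    base10 <- long |>
      dplyr::filter(.data$timepoint == "baseline",
                    .data$threshold == thresholds[
                      which.min(abs(thresholds - 0.10))])
    res[[length(res) + 1]] <-
      correlate(base10$education, base10[[metric]], "spearman") |>
      dplyr::mutate(family = "education", contrast = "education_baseline",
                    metric = metric,
                    threshold = thresholds[which.min(abs(thresholds - 0.10))])
  }
  out <- dplyr::bind_rows(res) |>
    dplyr::relocate("family", "contrast", "metric", "threshold")
  out |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(adjusted_p = {
      adj <- fdr_bh(tidyr::replace_na(.data$p_value, 1))
      adj[is.na(.data$p_value)] <- NA_real_
      adj
    }) |>
    dplyr::ungroup()
}

# completer-vs-control two-sample t on follow-up-minus-baseline
# differences, optionally residualized on education, gender, mean FD
did_contrast <- function(sub, cohort, metric, residualize) {
  both <- sub |> dplyr::filter(.data$completer |
                                 is_control_group(.data$group))
  d <- paired_differences(both, metric)
  info <- both |>
    dplyr::distinct(.data$participant_id, .data$group, .data$completer,
                    .data$education, .data$gender) |>
    dplyr::left_join(
      cohort |> dplyr::filter(.data$timepoint == "baseline") |>
        dplyr::select("participant_id", "mean_fd"),
      by = "participant_id") |>
    dplyr::filter(.data$participant_id %in% names(d)) |>
    dplyr::arrange(.data$participant_id)
  vals <- d[info$participant_id]
  if (residualize)
    vals <- residualize_confounds(
      vals, cbind(info$education, info$gender, info$mean_fd))
  tb <- tibble::tibble(
    participant_id = info$participant_id,
    group = ifelse(info$completer, "completer", "control"),
    value = vals)
  group_contrast(tb, "value", "two_sample_t")
}
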