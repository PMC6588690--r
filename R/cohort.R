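#' Cohort design for the synthetic study
#'
#' A two-timepoint (baseline / follow-up) design with training and control
#' groups. Training raises local-FC *integration* at follow-up by merging
#' the closest pairs of the participant's coherent patches (count down,
#' mean size up) — not by raising coupling amplitude. Education modulates
#' the baseline patch count (log-linearly), and mean head motion is mildly
#' coupled to baseline integration, so the classic confounds are present.
#'
#' @param n_per_group participants per group (>= 2).
#' @param groups group labels; groups whose name contains `"control"`
#'   never receive the training effect.
#' @param timepoints the two timepoint labels.
#' @param training_effect real in \[0, 1\]: the fraction of a
#'   completer's patches that merge with their nearest neighbour at
#'   follow-up (short bridges drawn between the closest pairs).
#'   Integration increases — count down, mean size up — while total
#'   coherent volume stays nearly constant.
#' @param education_slope change in log baseline patch count per year of
#'   education (negative: more education, fewer/larger patches).
#' @param attendance_max maximum attainable training sessions.
#' @param attendance_cutoff completion cut-off: completers attended more
#'   than this many sessions.
#' @param fraction_incomplete fraction of trainees below the cut-off.
#' @param gender_effect shift in log patch count for gender = 1.
#' @param fd_slope coupling of log mean-motion scale to baseline log
#'   patch count (z-scored).
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(n_per_group = 20,
                          groups = c("multi-domain", "single-domain", "control"),
                          timepoints = c("baseline", "follow-up"),
                          training_effect = 0.7,
                          education_slope = -0.04,
                          attendance_max = 27L,
                          attendance_cutoff = 19L,
                          fraction_incomplete = 0.25,
                          gender_effect = 0.03,
                          fd_slope = 0.15) {
  stopifnot(n_per_group >= 2, length(timepoints) == 2L,
            training_effect >= 0, training_effect <= 1,
            attendance_max > attendance_cutoff,
            fraction_incomplete >= 0, fraction_incomplete <= 1)
  structure(list(
    n_per_group = as.integer(n_per_group), groups = groups,
    timepoints = timepoints, training_effect = training_effect,
    education_slope = education_slope,
    attendance_max = as.integer(attendance_max),
    attendance_cutoff = as.integer(attendance_cutoff),
    fraction_incomplete = fraction_incomplete,
    gender_effect = gender_effect, fd_slope = fd_slope),
    class = "cohort_design")
}

is_control_group <- function(g) grepl("control", g, ignore.case = TRUE)

#' Simulate a two-group, two-timepoint cohort
#'
#' Draws per-participant demographics (age, gender, education), attendance
#' for trainees, and a participant-specific patch layout whose count
#' depends log-linearly on education (sizes are rescaled to a shared total
#' patch volume, so count and mean size trade off). Every participant
#' appears at both timepoints; trainees above the attendance cut-off get
#' follow-up volumes in which a `training_effect` fraction of patches have
#' merged with their nearest neighbour. The returned table carries the
#' ground-truth patch statistics and per-scan mean framewise displacement.
#'
#' Image bundles are regenerated deterministically from the per-row seeds:
#' call [cohort_bundle()] on a row index (or set `materialize = TRUE` for
#' small grids to embed them directly).
#'
#' @param design a [cohort_design()].
#' @param config a [simulation_config()]; its `seed` seeds the whole
#'   cohort, and `total_patch_volume` defaults to
#'   `round(0.105 * brain volume)` so planted patches roughly fill a top-10%
#'   threshold.
#' @param materialize if `TRUE`, also return the simulated image bundles
#'   (one per row; memory-heavy for large grids).
#' @return list with `cohort` (tibble, one row per participant x
#'   timepoint) and `bundles` (list of image bundles, or `NULL`).
#' @export
simulate_cohort <- function(design, config, materialize = FALSE) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(config, "simulation_config"))
  if (design$n_per_group < 2) abort("n_per_group must be >= 2.")
  n_groups <- length(design$groups)
  n <- design$n_per_group * n_groups

  if (is.null(config$total_patch_volume))
    config$total_patch_volume <-
      round(0.105 * sum(make_brain_mask(config$grid_shape)))

  per <- with_preserved_seed(config$seed, {
    group <- rep(design$groups, each = design$n_per_group)
    trainee <- !is_control_group(group)
    education <- pmin(pmax(round(rnorm(n, 10, 4)), 1), 22)
    age <- round(rnorm(n, 71, 3.8), 1)
    gender <- rbinom(n, 1, 0.5)
    log_n <- log(config$n_patches) +
      design$education_slope * (education - 10) +
      design$gender_effect * gender + rnorm(n, 0, 0.10)
    n_patches_i <- pmin(pmax(round(exp(log_n)), 5L),
                        as.integer(3 * config$n_patches))
    z <- as.numeric(scale(log(n_patches_i)))
    motion_scale <- exp(design$fd_slope * z + rnorm(n, 0, 0.15))
    attendance <- ifelse(
      trainee,
      ifelse(runif(n) < design$fraction_incomplete,
             sample(0:design$attendance_cutoff, n, replace = TRUE),
             sample((design$attendance_cutoff + 1):design$attendance_max,
                    n, replace = TRUE)),
      NA_integer_)
    tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      group = group, age = age, gender = gender, education = education,
      attendance = as.integer(attendance),
      completer = trainee & !is.na(attendance) &
        attendance > design$attendance_cutoff,
      n_patches_i = n_patches_i, motion_scale = motion_scale,
      layout_seed = config$seed + 7919L * seq_len(n))
  })

  rows <- tidyr::expand_grid(per, timepoint = design$timepoints) |>
    dplyr::mutate(
      merge_fraction = ifelse(
        .data$completer & .data$timepoint == design$timepoints[2],
        min(design$training_effect, 1), 0),
      noise_seed = .data$layout_seed + 13L +
        1000003L * match(.data$timepoint, design$timepoints))

  bundles <- if (materialize) vector("list", nrow(rows)) else NULL
  gt_n <- gt_mean <- mean_fd <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    b <- cohort_bundle_row(rows[i, ], config, images = materialize)
    gt_n[i] <- b$patches$n_patches
    gt_mean[i] <- b$patches$mean_size
    mean_fd[i] <- b$mean_fd
    if (materialize) bundles[[i]] <- b
  }
  cohort <- rows |>
    dplyr::mutate(gt_n_patches = gt_n, gt_mean_size = gt_mean,
                  mean_fd = mean_fd)
  list(cohort = cohort, bundles = bundles, config = config,
       design = design)
}

# Build (or rebuild) the image bundle for one cohort row. With
# images = FALSE only the layout, ground truth and motion/FD are computed.
cohort_bundle_row <- function(row, config, images = TRUE) {
  dims <- config$grid_shape
  brain <- make_brain_mask(dims)
  gm <- make_gm_mask(dims)
  cfg_i <- config
  cfg_i$n_patches <- if (!is.null(row$n_patches_i)) row$n_patches_i
                     else config$n_patches
  layout <- with_preserved_seed(row$layout_seed, {
    sizes <- draw_scaled_sizes(cfg_i)
    if (length(sizes)) place_patches(sizes, gm, dims)   # cortical patches
    else array(0L, dims)
  })
  if (row$merge_fraction > 0)
    layout <- with_preserved_seed(row$layout_seed + 17L,
      merge_nearest_pairs(layout, brain, row$merge_fraction))
  gt <- patch_ground_truth(layout)
  layout <- gt$labels   # merged components share one latent signal
  motion <- with_preserved_seed(row$noise_seed + 1L,
                                simulate_motion(config$n_timepoints,
                                                row$motion_scale))
  out <- list(participant_id = row$participant_id,
              timepoint = row$timepoint,
              brain_mask = brain, gm_mask = gm, motion = motion,
              patches = gt,
              mean_fd = mean(compute_fd(motion)))
  if (images) out$bold <- sim_images(cfg_i, layout,
                                     noise_seed = row$noise_seed)
  out
}

#' Regenerate the image bundle for one cohort row
#'
#' @param cohort_sim the list returned by [simulate_cohort()].
#' @param i row index into `cohort_sim$cohort`.
#' @return the image bundle for that participant x timepoint (see
#'   [simulate_participant()] for the fields, plus `mean_fd`).
#' @export
cohort_bundle <- function(cohort_sim, i) {
  cohort_bundle_row(cohort_sim$cohort[i, ], cohort_sim$config,
                    images = TRUE)
}

#' Write an image bundle to disk
#'
#' Writes the standard per-scan file set: 4D BOLD and 3D masks /
#' ground-truth patch labels as NIfTI, motion parameters as 6-column
#' whitespace-delimited text.
#'
#' @param bundle an image bundle from [simulate_participant()] or
#'   [cohort_bundle()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default: the participant id and
#'   timepoint if present).
#' @return invisibly, the vector of written paths.
#' @export
write_bundle <- function(bundle, dir, prefix = NULL) {
  if (is.null(prefix))
    prefix <- paste(c(bundle$participant_id, bundle$timepoint),
                    collapse = "_")
  if (!nzchar(prefix)) prefix <- "participant"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- bundle$bold$voxel_size_mm %||% c(3, 3, 3)
  paths <- c(
    bold = file.path(dir, paste0(prefix, "_bold.nii.gz")),
    brain = file.path(dir, paste0(prefix, "_brain_mask.nii.gz")),
    gm = file.path(dir, paste0(prefix, "_gm_mask.nii.gz")),
    patches = file.path(dir, paste0(prefix, "_patch_labels.nii.gz")),
    motion = file.path(dir, paste0(prefix, "_motion.txt")))
  write_nifti(bundle$bold, paths["bold"])
  write_nifti(bundle$brain_mask, paths["brain"], voxel_size_mm = vox)
  write_nifti(bundle$gm_mask, paths["gm"], voxel_size_mm = vox)
  write_nifti(bundle$patches$labels, paths["patches"], voxel_size_mm = vox)
  write_motion(bundle$motion, paths["motion"])
  invisible(paths)
}
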