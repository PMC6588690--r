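# Small fixture builders shared across test files.

tiny_config <- function(seed = 5, ...) {
  args <- utils::modifyList(
    list(grid_shape = c(16, 16, 16), n_timepoints = 40, n_patches = 12,
         size_min = 4, size_max = 60, coupling = 0.8, seed = seed),
    list(...))
  do.call(simulation_config, args)
}

tiny_design <- function(...) {
  args <- utils::modifyList(
    list(n_per_group = 3, groups = c("multi-domain", "control"),
         fraction_incomplete = 0),
    list(...))
  do.call(cohort_design, args)
}

# a reho_map built directly from a value array (full mask)
map_from_values <- function(values, resolution_mm = c(3, 3, 3)) {
  reho_map(values, array(TRUE, dim(values)),
           K_policy = list(min_neighbors = 27L),
           resolution_mm = resolution_mm)
}

# bold_series wrapping iid noise
noise_bold <- function(dims, nt, tr = 2, seed = 1) {
  withr::with_seed(seed,
    bold_series(array(rnorm(prod(dims) * nt), c(dims, nt)), tr_seconds = tr))
}
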