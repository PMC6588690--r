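#' Select the top fraction of ReHo voxels
#'
#' Marks exactly `round(fraction * n_defined)` voxels (round half up) with
#' the highest defined ReHo values. Ties at the cutoff are broken by
#' ascending linear voxel index, so the selection is deterministic.
#'
#' @param map a [reho_map()].
#' @param fraction scalar in (0, 1): e.g. 0.05, 0.10, 0.15, 0.20.
#' @return 3D logical array marking the selected voxels.
#' @export
threshold_top_fraction <- function(map, fraction) {
  stopifnot(inherits(map, "reho_map"))
  if (!(is.numeric(fraction) && length(fraction) == 1L &&
        fraction > 0 && fraction < 1))
    abort("`fraction` must be a scalar in (0, 1).")
  def <- which(!is.na(map$values))
  if (!length(def)) abort("map has no defined voxels.")
  n_sel <- floor(fraction * length(def) + 0.5)  # round half up
  out <- array(FALSE, dim(map$values))
  if (n_sel == 0L) return(out)
  ord <- def[order(-map$values[def], def)]
  out[ord[seq_len(n_sel)]] <- TRUE
  out
}

#' Constrain suprathreshold voxels to grey matter
#'
#' Voxel-wise intersection with the individual grey-matter mask. Because
#' cortical folding can make two anatomically distinct hot-spots touch
#' across a sulcus, this constraint may split one suprathreshold component
#' into several; it never merges components and can only remove voxels.
#'
#' @param supra 3D logical array of suprathreshold voxels.
#' @param gm_mask 3D logical grey-matter mask on the same grid.
#' @return 3D logical array.
#' @export
apply_gm_constraint <- function(supra, gm_mask) {
  if (!identical(dim(supra), dim(gm_mask)))
    abort("`supra` and `gm_mask` must share a grid.")
  supra & (gm_mask > 0)
}

#' Label connected suprathreshold clusters (HRCs)
#'
#' Partitions the selected voxels into maximal connected components under
#' 6-, 18- or 26-connectivity (default 26, consistent with the 3x3x3 ReHo
#' neighbourhood). Clusters are id-ordered by descending size, ties by
#' smallest linear voxel index. No minimum cluster size is imposed:
#' single-voxel clusters are retained.
#'
#' @param binary 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @param voxel_mm3 volume of one voxel in mm^3 (for `size_mm3`).
#' @return an object of class `hrc_set`: a list with `clusters` (tibble:
#'   `id`, `size_voxels`, `size_mm3`, `min_index`), `labels` (3D integer
#'   array, 0 = background), `n_clusters`, `mean_size`, `total_voxels`,
#'   `connectivity`, `voxel_mm3`.
#' @export
label_components <- function(binary, connectivity = 26L, voxel_mm3 = 27) {
  if (length(dim(binary)) != 3L) abort("`binary` must be a 3D array.")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    abort("`connectivity` must be 6, 18 or 26.")
  lab <- .label_components_cpp(as.logical(binary), as.integer(dim(binary)),
                               connectivity)
  lab <- array(lab, dim(binary))
  n <- max(lab)
  if (n == 0L) {
    clusters <- tibble::tibble(id = integer(), size_voxels = integer(),
                               size_mm3 = numeric(), min_index = integer())
  } else {
    size <- tabulate(lab, nbins = n)
    min_index <- rep(NA_integer_, n)
    fg <- which(lab > 0L)
    # scan order gives ascending linear index; first hit is the minimum
    first <- fg[!duplicated(lab[fg])]
    min_index[lab[first]] <- first
    ord <- order(-size, min_index)
    relabel <- integer(n)
    relabel[ord] <- seq_len(n)
    lab[fg] <- relabel[lab[fg]]
    clusters <- tibble::tibble(
      id = seq_len(n),
      size_voxels = size[ord],
      size_mm3 = size[ord] * voxel_mm3,
      min_index = min_index[ord])
  }
  total <- sum(clusters$size_voxels)
  structure(
    list(clusters = clusters, labels = lab,
         n_clusters = nrow(clusters),
         mean_size = if (nrow(clusters)) total / nrow(clusters) else NA_real_,
         total_voxels = total,
         connectivity = connectivity, voxel_mm3 = voxel_mm3),
    class = "hrc_set")
}

#' @export
print.hrc_set <- function(x, ...) {
  cat(sprintf(
    "<hrc_set> %d clusters, %d voxels total, mean size %.2f (connectivity %d)\n",
    x$n_clusters, x$total_voxels,
    if (is.na(x$mean_size)) NaN else x$mean_size, x$connectivity))
  invisible(x)
}

#' @method tidy hrc_set
#' @export
tidy.hrc_set <- function(x, ...) x$clusters

#' @method glance hrc_set
#' @export
glance.hrc_set <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters, mean_size = x$mean_size,
                 total_voxels = x$total_voxels,
                 connectivity = x$connectivity)
}

#' Extract high-ReHo clusters at one threshold
#'
#' Convenience wrapper: top-fraction threshold, optional grey-matter
#' constraint, connected-component labelling.
#'
#' @inheritParams threshold_top_fraction
#' @inheritParams label_components
#' @param gm_mask optional grey-matter mask; `NULL` skips the anatomical
#'   constraint.
#' @return an `hrc_set` with `threshold_fraction` and `gm_constrained`
#'   fields filled in.
#' @export
extract_hrcs <- function(map, fraction, gm_mask = NULL, connectivity = 26L) {
  supra <- threshold_top_fraction(map, fraction)
  if (!is.null(gm_mask)) supra <- apply_gm_constraint(supra, gm_mask)
  hs <- label_components(supra, connectivity,
                         voxel_mm3 = prod(map$resolution_mm))
  hs$threshold_fraction <- fraction
  hs$gm_constrained <- !is.null(gm_mask)
  hs
}

#' Voxel-wise mean HRC size across participants
#'
#' For each participant, every voxel is assigned the size of the HRC it
#' belongs to (0 if in none); the output averages these maps voxel-wise
#' across participants (zero-inclusive mean).
#'
#' @param hrc_sets list of `hrc_set` objects on a shared grid.
#' @return 3D numeric array of mean sizes.
#' @export
size_map <- function(hrc_sets) {
  if (!length(hrc_sets)) abort("need at least one participant.")
  dims <- dim(hrc_sets[[1]]$labels)
  acc <- array(0, dims)
  for (hs in hrc_sets) {
    if (!identical(dim(hs$labels), dims)) abort("grid mismatch across sets.")
    sz <- c(0, hs$clusters$size_voxels)
    acc <- acc + array(sz[hs$labels + 1L], dims)
  }
  acc / length(hrc_sets)
}

#' Network-wise HRC metrics
#'
#' Labels each cluster with every functional network it overlaps (>= 1
#' voxel) and summarizes per network: the number of overlapping clusters
#' and the mean overlap volume (overlap voxels, not full cluster sizes).
#' One cluster may count in several networks, so per-network counts need
#' not sum to the global cluster count.
#'
#' @param hrc_set an `hrc_set`.
#' @param template 3D integer array on the same grid; 0 = unassigned,
#'   1..8 = networks.
#' @param network_names optional character vector naming labels 1..n.
#' @return tibble: `network`, `network_name`, `n_clusters`,
#'   `mean_overlap_size`, `total_overlap_voxels`.
#' @export
network_metrics <- function(hrc_set, template,
                            network_names = c("MF", "FP", "DMN", "SC",
                                              "Mot", "V1", "V2", "Va")) {
  stopifnot(inherits(hrc_set, "hrc_set"))
  if (!identical(dim(template), dim(hrc_set$labels)))
    abort("template grid mismatch.")
  n_net <- max(length(network_names), max(template))
  fg <- hrc_set$labels > 0L & template > 0L
  out <- tibble::tibble(
    network = seq_len(n_net),
    network_name = if (n_net <= length(network_names))
      network_names[seq_len(n_net)] else as.character(seq_len(n_net)),
    n_clusters = 0L, mean_overlap_size = NA_real_,
    total_overlap_voxels = 0L)
  if (any(fg)) {
    agg <- tibble::tibble(cluster = hrc_set$labels[fg],
                          network = as.integer(template[fg])) |>
      dplyr::count(.data$cluster, .data$network, name = "overlap") |>
      dplyr::group_by(.data$network) |>
      dplyr::summarise(n_clusters = dplyr::n(),
                       mean_overlap_size = mean(.data$overlap),
                       total_overlap_voxels = sum(.data$overlap))
    out$n_clusters[agg$network] <- agg$n_clusters
    out$mean_overlap_size[agg$network] <- agg$mean_overlap_size
    out$total_overlap_voxels[agg$network] <- agg$total_overlap_voxels
  }
  out
}
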