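#' BOLD time-series container
#'
#' Wraps a 4D numeric array (x, y, z, time) together with its grid geometry
#' and repetition time. This is the raw input to preprocessing and to the
#' ReHo computation.
#'
#' @param data 4D numeric array, dimensions x, y, z, t with t >= 2.
#' @param voxel_size_mm numeric length-3, voxel edge lengths in mm.
#' @param tr_seconds positive scalar, repetition time in seconds.
#' @param space_tag free-text label for the space the volume lives in
#'   (e.g. `"native"`, `"MNI"`).
#'
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, voxel_size_mm = c(3, 3, 3), tr_seconds = 2,
                        space_tag = "native") {
  if (!is.array(data) || length(dim(data)) != 4L)
    abort("`data` must be a 4D array (x, y, z, t).")
  if (dim(data)[4] < 2L) abort("need at least 2 time points.")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    abort("`voxel_size_mm` must be 3 positive reals.")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    abort("`tr_seconds` must be a positive scalar.")
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm,
         tr_seconds = tr_seconds, space_tag = as.character(space_tag)),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bold_series> %d x %d x %d voxels, %d frames, TR = %gs, voxel %s mm, space '%s'\n",
    d[1], d[2], d[3], d[4], x$tr_seconds,
    paste(x$voxel_size_mm, collapse = "x"), x$space_tag))
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

n_frames <- function(series) dim(series$data)[4]

#' ReHo map container
#'
#' A 3D map of Kendall-concordance values in \[0, 1\] defined on in-mask
#' voxels; voxels where the map is undefined (outside the mask, or with an
#' incomplete neighbourhood under the edge policy) are `NA`, never
#' zero-filled.
#'
#' @param values 3D numeric array; `NA` where undefined.
#' @param mask 3D logical array, same grid.
#' @param K_policy list recording the neighbourhood rule used
#'   (`min_neighbors`).
#' @param resolution_mm numeric length-3 voxel size in mm.
#'
#' @return An object of class `reho_map`.
#' @export
reho_map <- function(values, mask, K_policy = list(min_neighbors = 27L),
                     resolution_mm = c(3, 3, 3)) {
  if (!identical(dim(values), dim(mask)))
    abort("`values` and `mask` must share a grid.")
  defined <- values[!is.na(values)]
  if (length(defined) && (min(defined) < -1e-9 || max(defined) > 1 + 1e-9))
    abort("defined ReHo values must lie in [0, 1].")
  structure(
    list(values = values, mask = as.array(mask) > 0, K_policy = K_policy,
         resolution_mm = as.numeric(resolution_mm)),
    class = "reho_map"
  )
}

#' @export
print.reho_map <- function(x, ...) {
  d <- dim(x$values)
  nd <- sum(!is.na(x$values))
  cat(sprintf(
    "<reho_map> %d x %d x %d grid (%s mm), %d defined voxels, min_neighbors = %d\n",
    d[1], d[2], d[3], paste(x$resolution_mm, collapse = "x"), nd,
    x$K_policy$min_neighbors))
  invisible(x)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' return/accept the package's containers. `read_bold()` expects a 4D
#' volume; `read_mask()` a 3D volume which is binarized at > 0.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param tr_seconds repetition time; if `NULL`, taken from the NIfTI
#'   header's 4th pixdim.
#' @param space_tag free-text space label.
#' @return `read_bold()`: a [bold_series()]; `read_mask()`: a logical 3D
#'   array with a `voxel_size_mm` attribute.
#' @export
read_bold <- function(path, tr_seconds = NULL, space_tag = "native") {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) abort("expected a 4D NIfTI volume.")
  pd <- RNifti::pixdim(img)
  if (is.null(tr_seconds)) tr_seconds <- if (length(pd) >= 4) pd[4] else 2
  arr <- as.array(img)
  bold_series(array(as.numeric(arr), dim(arr)), voxel_size_mm = pd[1:3],
              tr_seconds = tr_seconds, space_tag = space_tag)
}

#' @rdname read_bold
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) abort("expected a 3D NIfTI volume.")
  m <- unclass(as.array(img)) > 0
  attr(m, "voxel_size_mm") <- RNifti::pixdim(img)[1:3]
  m
}

#' @rdname read_bold
#' @param x a `bold_series`, `reho_map`, or plain 3D array to write.
#' @param voxel_size_mm voxel size used when writing a plain array.
#' @export
write_nifti <- function(x, path, voxel_size_mm = c(3, 3, 3)) {
  if (inherits(x, "bold_series")) {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- c(x$voxel_size_mm, x$tr_seconds)
  } else if (inherits(x, "reho_map")) {
    img <- RNifti::asNifti(x$values)
    RNifti::pixdim(img) <- x$resolution_mm
  } else {
    img <- RNifti::asNifti(x * 1)
    RNifti::pixdim(img) <- voxel_size_mm
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write 6-column rigid-body motion parameters
#'
#' Whitespace-delimited text, one row per frame: three translations (mm)
#' followed by three rotations (radians).
#'
#' @param path file path.
#' @return `read_motion()`: a t x 6 numeric matrix with columns
#'   `trans_x..rot_z`.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) abort("motion file must have exactly 6 columns.")
  dimnames(m) <- list(NULL,
    c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z"))
  m
}

#' @rdname read_motion
#' @param motion t x 6 numeric matrix.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(motion, digits = 10, scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
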