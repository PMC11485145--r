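#' Volume grid container
#'
#' A minimal 3D brain volume: a numeric array on a regular grid with voxel
#' sizes in millimetres. Volumes are held in a canonical orientation in which
#' array axis 1 is the rostro-caudal axis with anterior at index 1, so that
#' all seed-ordering logic reads a single axis. Voxel indices are 1-based in R
#' and coordinates refer to voxel centres.
#'
#' @param data numeric 3D array.
#' @param voxel_size_mm positive numeric vector of length 3 (mm per voxel
#'   along each array axis).
#' @param rc_axis which array axis of `data` is rostro-caudal; the array is
#'   permuted so this becomes axis 1.
#' @return An object of class `volume_grid` with elements `data` (3D array,
#'   axis 1 rostro-caudal) and `voxel_size_mm`.
#' @export
volume_grid <- function(data, voxel_size_mm = c(1, 1, 1), rc_axis = 1L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("volume data must be a 3D array, got %d dimension(s)",
          if (is.array(data)) length(dim(data)) else 1L)
  if (any(dim(data) < 1L)) stopf("all volume dimensions must be >= 1")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stopf("voxel_size_mm must be 3 positive finite numbers")
  rc_axis <- as.integer(rc_axis)
  if (!rc_axis %in% 1:3) stopf("rc_axis must be 1, 2 or 3")
  if (rc_axis != 1L) {
    perm <- c(rc_axis, setdiff(1:3, rc_axis))
    data <- aperm(data, perm)
    voxel_size_mm <- voxel_size_mm[perm]
  }
  structure(list(data = data, voxel_size_mm = voxel_size_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, %s mm (axis 1 = rostro-caudal)\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size_mm, 3), collapse = "x")))
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a NIfTI-1 file containing a 3D image.
#' @param rc_axis array axis holding the rostro-caudal direction in the file;
#'   the volume is reoriented on load so this is axis 1.
#' @return A [volume_grid].
#' @export
read_volume <- function(path, rc_axis = 1L) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stopf("expected a 3D image, %s has %d dimension(s)", path, length(d))
  vs <- RNifti::pixdim(img)[1:3]
  volume_grid(array(as.numeric(img), dim = d), voxel_size_mm = vs,
              rc_axis = rc_axis)
}

#' Write a volume grid to NIfTI
#'
#' Integer-valued volumes are stored as 32-bit integers and round-trip
#' bit-exactly through [read_volume()]; floating volumes are stored as
#' 64-bit doubles.
#'
#' @param vol a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  x <- vol$data
  integral <- all(is.finite(x)) && all(x == round(x)) &&
    max(abs(x)) < .Machine$integer.max
  if (integral) storage.mode(x) <- "integer"
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = if (integral) "int32" else "double")
  invisible(path)
}

#' 4D BOLD scan container
#'
#' Stores a 4D resting-state scan as a voxels-by-timepoints matrix plus the
#' spatial grid shape and repetition time. Voxels are in column-major (R
#' array) order of the canonical grid, so ROI voxel indices from a matching
#' [label_atlas] index rows of `data` directly.
#'
#' @param data numeric matrix, voxels x timepoints, or a 4D array.
#' @param grid_dim integer vector of length 3, the spatial grid shape.
#' @param tr_s repetition time in seconds.
#' @return An object of class `scan4d` with elements `data` (voxels x T
#'   matrix), `grid_dim`, `tr_s`.
#' @export
scan4d <- function(data, grid_dim, tr_s) {
  if (is.array(data) && length(dim(data)) == 4L) {
    grid_dim <- dim(data)[1:3]
    data <- matrix(data, nrow = prod(grid_dim))
  }
  if (!is.matrix(data)) stopf("scan data must be a matrix or 4D array")
  grid_dim <- as.integer(grid_dim)
  if (length(grid_dim) != 3L || prod(grid_dim) != nrow(data))
    stopf("grid_dim %s inconsistent with %d voxel rows",
          paste(grid_dim, collapse = "x"), nrow(data))
  if (ncol(data) < 2L) stopf("a scan needs >= 2 timepoints, got %d", ncol(data))
  tr_s <- as.numeric(tr_s)
  if (length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stopf("tr_s must be a single positive number")
  structure(list(data = data, grid_dim = grid_dim, tr_s = tr_s),
            class = "scan4d")
}

#' @export
print.scan4d <- function(x, ...) {
  cat(sprintf("<scan4d> grid %s, %d timepoints, TR %.3g s\n",
              paste(x$grid_dim, collapse = "x"), ncol(x$data), x$tr_s))
  invisible(x)
}

#' Read a 4D NIfTI scan
#'
#' @param path path to a 4D NIfTI file.
#' @param tr_s repetition time in seconds; taken from the header's fourth
#'   pixdim when `NULL`.
#' @return A [scan4d].
#' @export
read_scan <- function(path, tr_s = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stopf("expected a 4D image, %s has %d dimension(s)", path, length(d))
  if (is.null(tr_s)) {
    tr_s <- RNifti::pixdim(img)[4]
    if (!is.finite(tr_s) || tr_s <= 0)
      stopf("no usable repetition time in header of %s; pass tr_s", path)
  }
  scan4d(matrix(as.numeric(img), nrow = prod(d[1:3])), grid_dim = d[1:3],
         tr_s = tr_s)
}

#' Write a 4D scan to NIfTI
#'
#' @param scan a [scan4d].
#' @param path output path.
#' @param voxel_size_mm spatial voxel size triple.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(inherits(scan, "scan4d"))
  arr <- array(scan$data, dim = c(scan$grid_dim, ncol(scan$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_size_mm, scan$tr_s)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
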