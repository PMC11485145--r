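#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd rnorm approx pf var quantile ks.test runif
#' @importFrom utils read.delim write.table
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0

# linear voxel index <-> (i, j, k) helpers, 1-based, column-major
vox_index <- function(ijk, dim) {
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  (ijk[, 3L] - 1L) * dim[1L] * dim[2L] + (ijk[, 2L] - 1L) * dim[1L] + ijk[, 1L]
}

vox_coords <- function(idx, dim) {
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% dim[1L]
  j <- (idx0 %/% dim[1L]) %% dim[2L]
  k <- idx0 %/% (dim[1L] * dim[2L])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

# rank voxels along the rostro-caudal axis (array axis 1, anterior at index 1),
# ties broken by axes 2 then 3; returns normalized positions u = (rank - 0.5)/N
# in the input order of `idx`
voxel_u_positions <- function(idx, dim) {
  co <- vox_coords(idx, dim)
  r <- order(order(co[, 1L], co[, 2L], co[, 3L]))
  (r - 0.5) / length(idx)
}

pearson_safe <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
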