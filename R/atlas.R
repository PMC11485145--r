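ATLAS_HEMIS <- c("L", "R", "M")
ATLAS_ROLES <- c("seed_roi", "target", "sensory", "dmn", "other")

#' Label atlas container
#'
#' An integer-labelled 3D volume plus a label table. Label 0 is background
#' and never appears in the table; every non-zero grid value must. The table
#' records, per label, its name, hemisphere (`L`, `R`, or `M` for midline)
#' and functional role: `seed_roi` for the cingulate seed strip, `target`
#' for fingerprint target regions, `sensory`/`dmn` for the quality-control
#' networks, `other` otherwise.
#'
#' @param labels non-negative integer 3D array (canonical orientation: axis 1
#'   rostro-caudal, anterior first).
#' @param table data.frame with columns `label_id`, `name`, `hemisphere`,
#'   `role`.
#' @param voxel_size_mm positive numeric triple.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, table, voxel_size_mm = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stopf("atlas labels must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels)))
    stopf("atlas labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  need <- c("label_id", "name", "hemisphere", "role")
  if (!all(need %in% names(table)))
    stopf("label table must have columns %s", paste(need, collapse = ", "))
  table$label_id <- as.integer(table$label_id)
  if (anyDuplicated(table$label_id))
    stopf("duplicate label_id in label table")
  if (any(table$label_id == 0L))
    stopf("label 0 is background and must not appear in the table")
  if (!all(table$hemisphere %in% ATLAS_HEMIS))
    stopf("hemisphere must be one of %s", paste(ATLAS_HEMIS, collapse = ", "))
  if (!all(table$role %in% ATLAS_ROLES))
    stopf("role must be one of %s", paste(ATLAS_ROLES, collapse = ", "))
  used <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(used, table$label_id)
  if (length(missing))
    stopf("grid labels absent from table: %s", paste(missing, collapse = ", "))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stopf("voxel_size_mm must be 3 positive numbers")
  structure(list(labels = labels, table = table,
                 voxel_size_mm = voxel_size_mm),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %s voxels, %d labels (%d seed_roi, %d target)\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$table),
              sum(x$table$role == "seed_roi"), sum(x$table$role == "target")))
  invisible(x)
}

#' Read a label atlas from a NIfTI volume and TSV label table
#'
#' @param volume_path path to an integer-valued 3D NIfTI label volume.
#' @param table_path path to a TSV with columns `label_id`, `name`,
#'   `hemisphere`, `role`.
#' @param rc_axis see [read_volume()].
#' @return A [label_atlas].
#' @export
read_label_atlas <- function(volume_path, table_path, rc_axis = 1L) {
  vol <- read_volume(volume_path, rc_axis = rc_axis)
  if (any(vol$data != round(vol$data)))
    stopf("label volume %s is not integer-valued", volume_path)
  tab <- read.delim(table_path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
  label_atlas(vol$data, tab, voxel_size_mm = vol$voxel_size_mm)
}

#' Write a label atlas to NIfTI + TSV
#'
#' @param atlas a [label_atlas].
#' @param volume_path,table_path output paths.
#' @return `volume_path`, invisibly.
#' @export
write_label_atlas <- function(atlas, volume_path, table_path) {
  stopifnot(inherits(atlas, "label_atlas"))
  write_volume(volume_grid(atlas$labels, atlas$voxel_size_mm), volume_path)
  write.table(atlas$table, table_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(volume_path)
}

#' Voxel indices of one or more atlas labels
#'
#' @param atlas a [label_atlas].
#' @param label_ids integer label ids.
#' @return Sorted 1-based linear voxel indices into the atlas grid.
#' @export
atlas_voxels <- function(atlas, label_ids) {
  stopifnot(inherits(atlas, "label_atlas"))
  unknown <- setdiff(label_ids, atlas$table$label_id)
  if (length(unknown))
    stopf("unknown label id(s): %s", paste(unknown, collapse = ", "))
  which(atlas$labels %in% as.integer(label_ids))
}

#' Look up label ids by name or role
#'
#' @param atlas a [label_atlas].
#' @param name,role,hemisphere optional filters; non-NULL ones must all match.
#' @return Integer label ids.
#' @export
atlas_labels <- function(atlas, name = NULL, role = NULL, hemisphere = NULL) {
  stopifnot(inherits(atlas, "label_atlas"))
  tab <- atlas$table
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(name)) keep <- keep & tab$name %in% name
  if (!is.null(role)) keep <- keep & tab$role %in% role
  if (!is.null(hemisphere)) keep <- keep & tab$hemisphere %in% hemisphere
  tab$label_id[keep]
}
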