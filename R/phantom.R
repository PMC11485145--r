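# Default target-region names for the phantom, mirroring the nine regions a
# rodent cingulate fingerprint is typically built on. The first three zones
# of the default tracer rule set address the limbic, motor/striatal and
# hippocampal/visual groups respectively.
PHANTOM_TARGETS <- c("hippocampus", "amygdala", "accumbens", "hypothalamus",
                     "caudoputamen", "motor2", "parietal", "insula",
                     "orbitofrontal")

cube_span <- function(centre, side, lim) {
  half_lo <- (side - 1L) %/% 2L
  lo <- centre - half_lo
  hi <- lo + side - 1L
  if (lo < 1L || hi > lim) return(NULL)
  lo:hi
}

#' Build a phantom bilateral atlas with a cingulate-like seed strip
#'
#' Constructs a synthetic label atlas: one elongated midline seed strip
#' spanning at least 80% of the rostro-caudal (axis 1) extent, `n_targets`
#' compact cubic target regions per hemisphere (mirrored left/right when
#' `bilateral`), one somatosensory label per hemisphere (role `sensory`) and
#' one midline default-mode label (role `dmn`). Placement is on a fixed
#' lattice with a small seeded rostro-caudal jitter of the target positions;
#' the same `rng_seed` always yields the same atlas.
#'
#' @param grid_shape integer triple; axis 1 is rostro-caudal, axis 3
#'   left-right (midline between the two central slices).
#' @param n_targets number of named target regions (default 9; names beyond
#'   the built-in list are generated).
#' @param bilateral mirror targets and sensory labels into both hemispheres.
#' @param rng_seed integer seed for the placement jitter.
#' @param voxel_size_mm voxel size triple.
#' @return A [label_atlas].
#' @export
build_phantom_atlas <- function(grid_shape = c(40, 60, 30), n_targets = 9,
                                bilateral = TRUE, rng_seed = 1L,
                                voxel_size_mm = c(0.2, 0.2, 0.2)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            is_count(n_targets))
  nx <- grid_shape[1L]; ny <- grid_shape[2L]; nz <- grid_shape[3L]
  tnames <- if (n_targets <= length(PHANTOM_TARGETS))
    PHANTOM_TARGETS[seq_len(n_targets)]
  else c(PHANTOM_TARGETS,
         paste0("target", seq_len(n_targets - length(PHANTOM_TARGETS))))

  set.seed(as.integer(rng_seed))
  jitter_i <- if (n_targets > 0) sample(-1:1, n_targets, replace = TRUE)
              else integer(0)

  for (side in c(3L, 2L, 1L)) {
    lab <- array(0L, dim = grid_shape)
    rows <- list()
    ok <- TRUE
    place <- function(ix, jx, kx, id, name, hemi, role) {
      if (is.null(ix) || is.null(jx) || is.null(kx)) return(FALSE)
      if (any(lab[ix, jx, kx] != 0L)) return(FALSE)
      lab[ix, jx, kx] <<- id
      rows[[length(rows) + 1L]] <<- data.frame(
        label_id = id, name = name, hemisphere = hemi, role = role,
        stringsAsFactors = FALSE)
      TRUE
    }
    # seed strip: midline, >= 80% of the rostro-caudal extent, 2x2 section
    margin <- floor(0.08 * nx)
    i_strip <- (1L + margin):(nx - margin)
    j_strip <- cube_span(round(0.3 * ny), 2L, ny)
    k_strip <- cube_span(as.integer(ceiling((nz + 1) / 2)), 2L, nz)
    if (!place(i_strip, j_strip, k_strip, 1L, "cingulate_strip", "M",
               "seed_roi"))
      stopf("cannot place seed strip on a %s grid",
            paste(grid_shape, collapse = "x"))
    next_id <- 2L
    k_left <- max(1L, round(0.25 * nz))
    k_right <- nz + 1L - k_left
    j_rows <- c(round(0.35 * ny), round(0.7 * ny))
    hemis <- if (bilateral) c("L", "R") else "L"
    for (t in seq_len(n_targets)) {
      i_c <- max(2L, min(nx - 1L,
                         round((t - 0.5) / n_targets * nx) + jitter_i[t]))
      j_c <- j_rows[(t - 1L) %% 2L + 1L]
      for (h in hemis) {
        k_c <- if (h == "L") k_left else k_right
        ok <- ok && place(cube_span(i_c, side, nx), cube_span(j_c, side, ny),
                          cube_span(k_c, side, nz), next_id, tnames[t], h,
                          "target")
        next_id <- next_id + 1L
      }
      if (!ok) break
    }
    if (ok) {
      j_sens <- max(1L, round(0.1 * ny))
      for (h in hemis) {
        k_c <- if (h == "L") k_left else k_right
        ok <- ok && place(cube_span(round(0.3 * nx), side, nx),
                          cube_span(j_sens, side, ny),
                          cube_span(k_c, side, nz), next_id, "somatosensory",
                          h, "sensory")
        next_id <- next_id + 1L
      }
    }
    if (ok)
      ok <- place(cube_span(round(0.55 * nx), side, nx),
                  cube_span(min(ny - 1L, round(0.85 * ny)), side, ny),
                  k_strip, next_id, "dmn_medial", "M", "dmn")
    if (ok)
      return(label_atlas(lab, do.call(rbind, rows),
                         voxel_size_mm = voxel_size_mm))
  }
  stopf("cannot place %d targets without overlap on a %s grid", n_targets,
        paste(grid_shape, collapse = "x"))
}

#' Normalized rostro-caudal positions of seed-strip voxels
#'
#' Ranks the voxels of a label along array axis 1 (ties broken by axes 2,
#' then 3) and returns u = (rank - 0.5) / N for each voxel, in voxel-index
#' order.
#'
#' @param atlas a [label_atlas].
#' @param label_id label to rank (default: the `seed_roi` label).
#' @return data.frame with columns `voxel` (linear index) and `u`.
#' @export
strip_positions <- function(atlas, label_id = NULL) {
  if (is.null(label_id)) {
    label_id <- atlas_labels(atlas, role = "seed_roi")
    if (length(label_id) != 1L)
      stopf("atlas must have exactly one seed_roi label, found %d",
            length(label_id))
  }
  vox <- atlas_voxels(atlas, label_id)
  if (!length(vox)) stopf("label %d has no voxels", label_id)
  data.frame(voxel = vox, u = voxel_u_positions(vox, dim(atlas$labels)))
}
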