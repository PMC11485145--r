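#' Place seeds at even intervals along a region of interest
#'
#' ROI voxels are ranked along the rostro-caudal axis (array axis 1,
#' anterior first; ties broken by axes 2 then 3) and seeds are taken at the
#' rank quantiles `q_i = (i - 0.5) / n_seeds`, i.e. 1-based rank
#' `ceiling(q_i * N)` among the `N` ROI voxels. Each seed is a single voxel
#' by default; `radius > 0` grows it to the ROI voxels within that Chebyshev
#' radius. "Even intervals" is thus interpreted on the rank axis, which is
#' well defined for any ROI shape and reduces to arc length on a straight
#' strip.
#'
#' @param atlas a [label_atlas].
#' @param roi_label_ids label id(s) forming the ROI (default: the `seed_roi`
#'   label).
#' @param n_seeds number of seeds; must not exceed the ROI voxel count.
#' @param radius optional growth radius in voxels.
#' @return An object of class `seed_spec`: list with `seeds` (list of voxel
#'   index vectors) and `u` (strictly increasing normalized positions
#'   `(i - 0.5) / n_seeds`).
#' @export
place_seeds <- function(atlas, roi_label_ids = NULL, n_seeds, radius = 0) {
  stopifnot(inherits(atlas, "label_atlas"), is_count(n_seeds), n_seeds >= 1)
  if (is.null(roi_label_ids))
    roi_label_ids <- atlas_labels(atlas, role = "seed_roi")
  vox <- atlas_voxels(atlas, roi_label_ids)
  N <- length(vox)
  if (n_seeds > N)
    stopf("n_seeds (%d) exceeds ROI voxel count (%d)", n_seeds, N)
  dims <- dim(atlas$labels)
  co <- vox_coords(vox, dims)
  ranked <- vox[order(co[, 1L], co[, 2L], co[, 3L])]
  q <- (seq_len(n_seeds) - 0.5) / n_seeds
  # rank quantiles; integer numerator avoids floating-point ceiling slips
  centres <- ranked[ceiling((2 * seq_len(n_seeds) - 1) * N / (2 * n_seeds))]
  seeds <- as.list(centres)
  if (radius > 0) {
    cco <- vox_coords(centres, dims)
    for (i in seq_len(n_seeds)) {
      d <- pmax(abs(co[, 1L] - cco[i, 1L]), abs(co[, 2L] - cco[i, 2L]),
                abs(co[, 3L] - cco[i, 3L]))
      seeds[[i]] <- vox[d <= radius]
    }
    if (anyDuplicated(unlist(seeds)))
      stopf("radius %g makes seed sets overlap; reduce radius or n_seeds",
            radius)
  }
  structure(list(seeds = seeds, u = q), class = "seed_spec")
}

#' Sample mean tracer density at a set of locations
#'
#' @param experiments list of `tracer_experiment` objects (or bare 3D
#'   density arrays).
#' @param locations list of voxel-index vectors (or a [place_seeds()]
#'   `seed_spec`, whose seed sets are used).
#' @return experiments x locations numeric matrix (class
#'   `projection_matrix`); entry (e, l) is the mean density of experiment e
#'   over the voxels of location l. Carries the location voxel sets as the
#'   `locations` attribute.
#' @export
sample_density <- function(experiments, locations) {
  if (inherits(locations, "seed_spec")) locations <- locations$seeds
  if (!length(experiments)) stopf("no experiments")
  if (!length(locations)) stopf("no locations")
  dens <- lapply(experiments, function(e)
    if (inherits(e, "tracer_experiment")) e$density else e)
  nv <- length(dens[[1L]])
  sizes <- lengths(locations)
  if (any(sizes == 0L)) stopf("empty location set")
  allv <- unlist(locations, use.names = FALSE)
  if (any(allv < 1L) || any(allv > nv)) stopf("location voxel outside grid")
  D <- do.call(rbind, lapply(dens, as.vector))  # experiments x voxels
  if (all(sizes == 1L)) {
    out <- D[, allv, drop = FALSE]
  } else {
    out <- vapply(locations, function(v) {
      if (length(v) == 1L) D[, v] else rowMeans(D[, v, drop = FALSE])
    }, numeric(nrow(D)))
    out <- matrix(out, nrow = nrow(D))
  }
  dimnames(out) <- list(NULL, names(locations))
  structure(out, class = c("projection_matrix", "matrix"),
            locations = locations)
}

#' Projection-similarity map
#'
#' Correlates, across tracer experiments, the density recorded at each seed
#' with the density recorded at each brain location: entry (s, v) is the
#' Pearson correlation between seed column s and location column v. A
#' location (or seed) whose density is constant across experiments yields
#' `NA` for all its entries. High similarity means the two locations
#' receive projections from the same injection sites.
#'
#' @param seed_densities experiments x seeds [sample_density()] matrix.
#' @param brain_densities experiments x locations matrix sharing the same
#'   experiment dimension; needs >= 3 experiments.
#' @param seed_u optional normalized seed positions to carry along.
#' @return An object of class `similarity_map`: list with `values` (seeds x
#'   locations, entries in `[-1, 1]` or `NA`), `voxels` (the brain-side
#'   location sets), `seed_u`.
#' @export
projection_similarity <- function(seed_densities, brain_densities,
                                  seed_u = NULL) {
  seed_densities <- unclass(seed_densities)
  locs <- attr(brain_densities, "locations")
  brain_densities <- unclass(brain_densities)
  if (nrow(seed_densities) != nrow(brain_densities))
    stopf("seed and brain matrices must share the experiment dimension")
  if (nrow(seed_densities) < 3L)
    stopf("need >= 3 experiments to correlate, got %d", nrow(seed_densities))
  vals <- suppressWarnings(stats::cor(seed_densities, brain_densities))
  const_seed <- apply(seed_densities, 2L, stats::sd) == 0
  const_brain <- apply(brain_densities, 2L, stats::sd) == 0
  vals[const_seed, ] <- NA_real_
  vals[, const_brain] <- NA_real_
  structure(list(values = vals, voxels = locs, seed_u = seed_u),
            class = "similarity_map")
}

#' @export
print.similarity_map <- function(x, ...) {
  cat(sprintf("<similarity_map> %d seeds x %d locations (%d NA columns)\n",
              nrow(x$values), ncol(x$values),
              sum(colSums(is.na(x$values)) == nrow(x$values))))
  invisible(x)
}

#' Tracer connectivity fingerprint
#'
#' Correlates, over non-excluded brain voxels, each seed's whole-brain
#' similarity row with each target's whole-brain similarity row. The
#' excluded support (at minimum the seed strip and the target labels
#' themselves) removes self-correlation inflation so entries are comparable
#' across targets. `NA` voxels are dropped pairwise.
#'
#' @param sim_seeds [projection_similarity()] map for the fingerprint seeds.
#' @param sim_targets similarity map for the target regions, on the same
#'   brain-location support (single-voxel locations).
#' @param exclude_voxels voxel indices removed from the correlation support.
#' @param seed_positions normalized seed positions (defaults to
#'   `sim_seeds$seed_u`).
#' @param target_names names for the fingerprint columns.
#' @param species tag recorded on the fingerprint.
#' @return A [fingerprint] with `sem = NA` and `n = 1` (single measurement).
#' @export
tracer_fingerprint <- function(sim_seeds, sim_targets, exclude_voxels,
                               seed_positions = NULL, target_names = NULL,
                               species = NA_character_) {
  stopifnot(inherits(sim_seeds, "similarity_map"),
            inherits(sim_targets, "similarity_map"))
  if (ncol(sim_seeds$values) != ncol(sim_targets$values))
    stopf("similarity maps must share the brain-location support")
  support_vox <- unlist(sim_seeds$voxels, use.names = FALSE)
  keep <- !(support_vox %in% exclude_voxels)
  if (sum(keep) < 10L)
    stopf("fewer than 10 non-excluded voxels (%d)", sum(keep))
  A <- sim_seeds$values[, keep, drop = FALSE]
  B <- sim_targets$values[, keep, drop = FALSE]
  vals <- suppressWarnings(
    stats::cor(t(A), t(B), use = "pairwise.complete.obs"))
  if (is.null(seed_positions)) seed_positions <- sim_seeds$seed_u
  if (is.null(seed_positions))
    stopf("seed_positions needed (sim_seeds carries no seed_u)")
  if (!is.null(target_names)) colnames(vals) <- target_names
  fingerprint(vals, sem = NULL, n = 1L, seed_positions = seed_positions,
              species = species, modality = "tracer")
}

#' Single-voxel brain support for similarity mapping
#'
#' Convenience constructor of the brain-side location list: one single-voxel
#' location per (optionally masked) grid voxel.
#'
#' @param atlas a [label_atlas].
#' @param mask optional logical array or voxel index vector restricting the
#'   support.
#' @return List of length-1 voxel index vectors.
#' @export
brain_locations <- function(atlas, mask = NULL) {
  nv <- length(atlas$labels)
  idx <- if (is.null(mask)) seq_len(nv)
  else if (is.logical(mask)) which(mask)
  else as.integer(mask)
  as.list(idx)
}
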