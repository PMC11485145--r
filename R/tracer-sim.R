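#' Tracer rule set: how injection position maps to projection targets
#'
#' A rule set is a list of rostro-caudal zones. An injection at normalized
#' strip position `u` delivers density
#' `strength * exp(-(u - u_center)^2 / (2 * u_width^2))` to every voxel of
#' every target region named by the zone, on top of a constant background
#' density everywhere and additive Gaussian noise truncated at zero. The
#' injected strip itself records a local tracer bolus of amplitude
#' `injection_amplitude` decaying with Gaussian width `injection_sigma`
#' along `u`, so strip voxels close in `u` covary across experiments.
#'
#' @param zones list of zones created by [tracer_zone()].
#' @param background_density constant non-negative baseline density.
#' @param noise_sd standard deviation of the additive voxelwise noise.
#' @param injection_amplitude,injection_sigma local bolus parameters at the
#'   injection site (in density units and `u` units respectively).
#' @return An object of class `tracer_ruleset`.
#' @export
tracer_ruleset <- function(zones, background_density = 0.05, noise_sd = 0,
                           injection_amplitude = 2, injection_sigma = 0.12) {
  if (!length(zones)) stopf("a tracer rule set needs at least one zone")
  for (z in zones) {
    if (!inherits(z, "tracer_zone")) stopf("zones must be tracer_zone objects")
  }
  stopifnot(background_density >= 0, noise_sd >= 0, injection_amplitude >= 0,
            injection_sigma > 0)
  structure(list(zones = zones, background_density = background_density,
                 noise_sd = noise_sd,
                 injection_amplitude = injection_amplitude,
                 injection_sigma = injection_sigma),
            class = "tracer_ruleset")
}

#' @rdname tracer_ruleset
#' @param u_center zone centre on the normalized rostro-caudal axis, in
#'   `[0, 1]`.
#' @param u_width positive Gaussian width of the zone along `u`.
#' @param targets character vector of target region names (atlas `name`
#'   column; both hemispheres of a named region receive density).
#' @param strength peak density delivered at `u = u_center`.
#' @export
tracer_zone <- function(u_center, u_width, targets, strength = 1) {
  stopifnot(u_center >= 0, u_center <= 1, u_width > 0, strength >= 0,
            length(targets) >= 1)
  structure(list(u_center = u_center, u_width = u_width,
                 targets = as.character(targets), strength = strength),
            class = "tracer_zone")
}

#' Default three-zone rule sets for the phantom species
#'
#' The mouse-analogue rule set routes anterior injections to limbic targets
#' (amygdala, accumbens, orbitofrontal and, in the mouse, insula),
#' mid-strip injections to motor/striatal targets (motor2, caudoputamen,
#' parietal) and posterior injections to hippocampal/diencephalic targets.
#' The human-analogue set is identical except the insula is wired to the
#' mid-cingulate zone, the planted analogue of the clearest cross-species
#' dissociation the comparator is meant to pick up.
#'
#' @param species `"mouse"` or `"human"`.
#' @param noise_sd voxelwise density noise (default 0.2 of unit strength).
#' @return A [tracer_ruleset].
#' @export
default_tracer_rules <- function(species = c("mouse", "human"),
                                 noise_sd = 0.2) {
  species <- match.arg(species)
  anterior <- c("amygdala", "accumbens", "orbitofrontal")
  mid <- c("motor2", "caudoputamen", "parietal")
  if (species == "mouse") anterior <- c(anterior, "insula")
  else mid <- c(mid, "insula")
  tracer_ruleset(
    zones = list(
      tracer_zone(0.15, 0.15, anterior),
      tracer_zone(0.50, 0.15, mid),
      tracer_zone(0.85, 0.15, c("hippocampus", "hypothalamus"))),
    background_density = 0.05, noise_sd = noise_sd)
}

#' Simulate a collection of anterograde tracer experiments
#'
#' Injection positions are stratified along the strip (evenly spaced with a
#' small seeded jitter) so that even small collections cover the whole
#' rostro-caudal extent. A configurable fraction of experiments is injected
#' off-strip (background-only density, `injection_u` recorded as `NA`).
#' Densities are truncated at zero.
#'
#' @param atlas a [label_atlas] with one `seed_roi` strip label.
#' @param rules a [tracer_ruleset].
#' @param n_experiments number of experiments (>= 1).
#' @param rng_seed integer seed; identical seeds give bit-identical output.
#' @param frac_off_strip fraction of experiments injected outside the strip.
#' @return List of `tracer_experiment` objects, each with elements `density`
#'   (3D array), `injection_voxels`, `injection_u`, `off_strip`. The list
#'   carries a `manifest` attribute (data.frame: experiment_id, injection_u,
#'   off_strip).
#' @export
simulate_tracer_experiments <- function(atlas, rules, n_experiments,
                                        rng_seed = 1L, frac_off_strip = 0) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(rules, "tracer_ruleset"),
            is_count(n_experiments), n_experiments >= 1,
            frac_off_strip >= 0, frac_off_strip <= 1)
  strip <- strip_positions(atlas)
  dims <- dim(atlas$labels)
  # resolve zone targets once; unknown names are configuration errors
  zone_vox <- lapply(rules$zones, function(z) {
    ids <- atlas_labels(atlas, name = z$targets)
    found <- unique(atlas$table$name[atlas$table$label_id %in% ids])
    missing <- setdiff(z$targets, found)
    if (length(missing))
      stopf("tracer rule references unknown target label(s): %s",
            paste(missing, collapse = ", "))
    atlas_voxels(atlas, ids)
  })
  off_vox_pool <- which(atlas$labels == 0L)

  set.seed(as.integer(rng_seed))
  n_off <- round(frac_off_strip * n_experiments)
  off_flag <- rep(FALSE, n_experiments)
  if (n_off > 0)
    off_flag[sample.int(n_experiments, n_off)] <- TRUE
  u_inj <- (seq_len(n_experiments) - 0.5) / n_experiments +
    stats::runif(n_experiments, -0.5, 0.5) / n_experiments
  u_inj <- pmin(1, pmax(0, u_inj))

  experiments <- vector("list", n_experiments)
  for (e in seq_len(n_experiments)) {
    dens <- array(rules$background_density, dim = dims)
    if (off_flag[e]) {
      inj <- sample(off_vox_pool, 1L)
      u_e <- NA_real_
    } else {
      u_e <- u_inj[e]
      inj <- strip$voxel[abs(strip$u - u_e) <= 0.02]
      if (!length(inj)) inj <- strip$voxel[which.min(abs(strip$u - u_e))]
      for (zi in seq_along(rules$zones)) {
        z <- rules$zones[[zi]]
        dens[zone_vox[[zi]]] <- dens[zone_vox[[zi]]] +
          z$strength * exp(-(u_e - z$u_center)^2 / (2 * z$u_width^2))
      }
      dens[strip$voxel] <- dens[strip$voxel] + rules$injection_amplitude *
        exp(-(strip$u - u_e)^2 / (2 * rules$injection_sigma^2))
    }
    if (rules$noise_sd > 0)
      dens <- dens + array(stats::rnorm(length(dens), sd = rules$noise_sd),
                           dim = dims)
    dens[dens < 0] <- 0
    experiments[[e]] <- structure(
      list(density = dens, injection_voxels = inj, injection_u = u_e,
           off_strip = off_flag[e]),
      class = "tracer_experiment")
  }
  attr(experiments, "manifest") <- data.frame(
    experiment_id = seq_len(n_experiments),
    injection_u = ifelse(off_flag, NA_real_, u_inj),
    off_strip = off_flag)
  experiments
}

#' Write tracer experiments to NIfTI volumes plus a manifest TSV
#'
#' @param experiments output of [simulate_tracer_experiments()].
#' @param dir output directory (created if needed).
#' @param voxel_size_mm voxel size triple for the NIfTI headers.
#' @return Path of the manifest TSV, invisibly.
#' @export
write_tracer_experiments <- function(experiments, dir,
                                     voxel_size_mm = c(1, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- attr(experiments, "manifest")
  if (is.null(man))
    man <- data.frame(experiment_id = seq_along(experiments),
                      injection_u = vapply(experiments, `[[`, 0, "injection_u"),
                      off_strip = vapply(experiments, `[[`, NA, "off_strip"))
  man$path <- file.path(dir, sprintf("experiment_%03d.nii.gz",
                                     man$experiment_id))
  for (e in seq_along(experiments))
    write_volume(volume_grid(experiments[[e]]$density, voxel_size_mm),
                 man$path[e])
  manifest_path <- file.path(dir, "experiments.tsv")
  write.table(man, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(manifest_path)
}
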