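#' BOLD covariance model for synthetic resting-state scans
#'
#' Each network owns one latent timecourse (unit-variance Gaussian white
#' series). A voxel assigned to a network records
#' `loading * signal_sd[network] * latent + white noise (sd = noise_sd)`.
#' Voxels of homotopic left/right regions assigned to the same network share
#' one latent, planting homotopic coupling; networks listed in
#' `anticorrelated_pairs` share a latent with negated sign, planting e.g.
#' the sensory-versus-default-mode anticorrelation axis. A `frac_bad`
#' fraction of scans is generated as pure noise ("non-specific" scans) and
#' flagged in the returned metadata.
#'
#' Assignment rows may optionally carry a `u_min`/`u_max` range: such rows
#' apply only to the voxels of the (seed-strip) label whose normalized
#' rostro-caudal position falls in `[u_min, u_max)`, which is how
#' position-dependent coupling of the cingulate strip to different networks
#' is planted. A row may also carry `private` (default 0): the standard
#' deviation of an additional latent shared only within that row's voxels,
#' modelling region-specific fluctuations that dilute the region's coupling
#' to its network below the coupling of the network's core region.
#'
#' @param assignment data.frame with columns `label_id`, `network`
#'   (character), and optionally `loading` (default 1), `private`
#'   (default 0), `u_min`, `u_max`.
#' @param signal_sd named numeric vector of per-network latent scales, or a
#'   single value recycled to all networks.
#' @param noise_sd positive white-noise standard deviation.
#' @param anticorrelated_pairs list of length-2 character vectors naming
#'   network pairs with negated shared latents.
#' @param frac_bad fraction of scans generated as pure noise, in `[0, 1]`.
#' @return An object of class `bold_model`.
#' @export
bold_model <- function(assignment, signal_sd = 1, noise_sd = 1,
                       anticorrelated_pairs = list(), frac_bad = 0) {
  assignment <- as.data.frame(assignment, stringsAsFactors = FALSE)
  if (!all(c("label_id", "network") %in% names(assignment)))
    stopf("assignment needs columns label_id, network")
  if (is.null(assignment$loading)) assignment$loading <- 1
  if (is.null(assignment$private)) assignment$private <- 0
  if (is.null(assignment$u_min)) assignment$u_min <- NA_real_
  if (is.null(assignment$u_max)) assignment$u_max <- NA_real_
  networks <- unique(assignment$network)
  if (length(signal_sd) == 1L && is.null(names(signal_sd)))
    signal_sd <- stats::setNames(rep(signal_sd, length(networks)), networks)
  if (!all(networks %in% names(signal_sd)))
    stopf("signal_sd must name every network")
  stopifnot(all(signal_sd >= 0), noise_sd > 0, frac_bad >= 0, frac_bad <= 1)
  for (p in anticorrelated_pairs) {
    if (length(p) != 2L || !all(p %in% networks))
      stopf("anticorrelated pairs must name two known networks")
  }
  structure(list(assignment = assignment, signal_sd = signal_sd,
                 noise_sd = noise_sd,
                 anticorrelated_pairs = anticorrelated_pairs,
                 frac_bad = frac_bad),
            class = "bold_model")
}

#' Default phantom BOLD model
#'
#' Plants the rostro-caudal connectivity gradient of the phantom: the
#' anterior third of the seed strip shares the `limbic` latent with the
#' amygdala (accumbens and orbitofrontal load on it more weakly), the middle
#' third shares the `motor` latent with motor2 (caudoputamen and parietal
#' weaker), the posterior third shares the `posterior` latent with the
#' hippocampus (hypothalamus weaker). The left/right somatosensory labels
#' share one `sensory` latent (homotopic coupling) and the default-mode
#' label is anticorrelated with it. In the human-analogue model the insula
#' loads on the mid-cingulate `motor` network instead of the anterior
#' `limbic` network.
#'
#' @param atlas a phantom [label_atlas] from [build_phantom_atlas()].
#' @param species `"mouse"` or `"human"`.
#' @param signal_sd,noise_sd latent and noise scales (defaults 1 and 1).
#' @param frac_bad fraction of pure-noise scans.
#' @return A [bold_model].
#' @export
default_bold_model <- function(atlas, species = c("mouse", "human"),
                               signal_sd = 1, noise_sd = 1, frac_bad = 0) {
  species <- match.arg(species)
  strip_id <- atlas_labels(atlas, role = "seed_roi")
  id_of <- function(nm) atlas_labels(atlas, name = nm)
  row <- function(ids, network, loading = 1, private = 0, u_min = NA,
                  u_max = NA)
    data.frame(label_id = ids, network = network, loading = loading,
               private = private, u_min = u_min, u_max = u_max)
  insula_net <- if (species == "mouse") "limbic" else "motor"
  part <- function(loading) sqrt(1 - loading^2)  # unit total variance
  assignment <- rbind(
    row(strip_id, "limbic", 1, u_min = 0, u_max = 1 / 3),
    row(strip_id, "motor", 1, u_min = 1 / 3, u_max = 2 / 3),
    row(strip_id, "posterior", 1, u_min = 2 / 3, u_max = 1),
    row(id_of("amygdala"), "limbic", 1),
    row(id_of("accumbens"), "limbic", 0.6, part(0.6)),
    row(id_of("orbitofrontal"), "limbic", 0.35, part(0.35)),
    row(id_of("insula"), insula_net, 0.5, part(0.5)),
    row(id_of("motor2"), "motor", 1),
    row(id_of("caudoputamen"), "motor", 0.6, part(0.6)),
    row(id_of("parietal"), "motor", 0.35, part(0.35)),
    row(id_of("hippocampus"), "posterior", 1),
    row(id_of("hypothalamus"), "posterior", 0.6, part(0.6)),
    row(id_of("somatosensory"), "sensory", 1),
    row(id_of("dmn_medial"), "dmn", 1))
  bold_model(assignment, signal_sd = signal_sd, noise_sd = noise_sd,
             anticorrelated_pairs = list(c("sensory", "dmn")),
             frac_bad = frac_bad)
}

# Resolve a bold_model against an atlas into voxel groups; checks that every
# target/sensory/dmn label is assigned to a network.
bold_sim_prepare <- function(atlas, model) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(model, "bold_model"))
  need <- atlas_labels(atlas, role = c("target", "sensory", "dmn"))
  unassigned <- setdiff(need, model$assignment$label_id)
  if (length(unassigned))
    stopf("target/sensory/dmn label(s) not assigned to a network: %s",
          paste(unassigned, collapse = ", "))
  unknown <- setdiff(model$assignment$label_id, atlas$table$label_id)
  if (length(unknown))
    stopf("bold model references unknown label(s): %s",
          paste(unknown, collapse = ", "))
  networks <- unique(model$assignment$network)
  # anticorrelated networks reuse the partner's latent with negated loading
  latent_of <- stats::setNames(seq_along(networks), networks)
  latent_sign <- stats::setNames(rep(1, length(networks)), networks)
  for (p in model$anticorrelated_pairs) {
    latent_of[p[2L]] <- latent_of[p[1L]]
    latent_sign[p[2L]] <- -1
  }
  n_latents <- length(networks)
  groups <- vector("list", nrow(model$assignment))
  for (r in seq_len(nrow(model$assignment))) {
    a <- model$assignment[r, ]
    vox <- atlas_voxels(atlas, a$label_id)
    if (!is.na(a$u_min)) {
      u <- voxel_u_positions(vox, dim(atlas$labels))
      vox <- vox[u >= a$u_min & u < a$u_max]
    }
    private_latent <- 0L
    if (a$private > 0) {
      n_latents <- n_latents + 1L
      private_latent <- n_latents
    }
    groups[[r]] <- list(
      vox = vox,
      latent = latent_of[[a$network]],
      scale = latent_sign[[a$network]] * a$loading *
        model$signal_sd[[a$network]],
      private_latent = private_latent,
      private_scale = a$private * model$signal_sd[[a$network]])
  }
  list(groups = groups, n_latents = n_latents,
       n_vox = length(atlas$labels), noise_sd = model$noise_sd)
}

# Draw one scan's voxels x timepoints matrix from the prepared model.
bold_sim_draw <- function(prep, n_timepoints, bad = FALSE) {
  x <- matrix(stats::rnorm(prep$n_vox * n_timepoints, sd = prep$noise_sd),
              nrow = prep$n_vox)
  if (!bad) {
    latents <- matrix(stats::rnorm(prep$n_latents * n_timepoints),
                      nrow = prep$n_latents)
    for (g in prep$groups) {
      if (!length(g$vox)) next
      s <- numeric(ncol(x))
      if (g$scale != 0) s <- s + g$scale * latents[g$latent, ]
      if (g$private_latent > 0L && g$private_scale != 0)
        s <- s + g$private_scale * latents[g$private_latent, ]
      x[g$vox, ] <- x[g$vox, ] + rep(s, each = length(g$vox))
    }
  }
  x
}

#' Simulate a cohort of resting-state BOLD scans
#'
#' @param atlas a [label_atlas].
#' @param model a [bold_model]; see [default_bold_model()].
#' @param n_subjects number of scans.
#' @param n_timepoints timepoints per scan (>= 16).
#' @param tr_s repetition time in seconds.
#' @param rng_seed integer seed; identical seeds give bit-identical scans.
#' @return List of [scan4d] objects, each with an extra element `bad`; the
#'   list carries a `manifest` attribute (subject_id, bad, tr_s).
#' @export
simulate_rsfmri_scans <- function(atlas, model, n_subjects, n_timepoints,
                                  tr_s = 1, rng_seed = 1L) {
  stopifnot(is_count(n_subjects), n_subjects >= 1)
  if (n_timepoints < 16L) stopf("n_timepoints must be >= 16")
  prep <- bold_sim_prepare(atlas, model)
  set.seed(as.integer(rng_seed))
  bad <- bad_scan_flags(model$frac_bad, n_subjects)
  scans <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sc <- scan4d(bold_sim_draw(prep, n_timepoints, bad[s]),
                 grid_dim = dim(atlas$labels), tr_s = tr_s)
    sc$bad <- bad[s]
    scans[[s]] <- sc
  }
  attr(scans, "manifest") <- data.frame(subject_id = seq_len(n_subjects),
                                        bad = bad, tr_s = tr_s)
  scans
}

bad_scan_flags <- function(frac_bad, n) {
  bad <- rep(FALSE, n)
  n_bad <- round(frac_bad * n)
  if (n_bad > 0) bad[sample.int(n, n_bad)] <- TRUE
  bad
}
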