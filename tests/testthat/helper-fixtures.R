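# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# standard tracer-scale phantom
phantom_atlas <- function() memo("atlas40", build_phantom_atlas())

# compact phantom for fMRI cohorts
fmri_atlas <- function() memo("atlas24", build_phantom_atlas(c(24, 30, 16)))

# small phantom for QC cohorts
qc_atlas <- function() memo("atlas16", build_phantom_atlas(c(16, 18, 12)))

# a hand-built minimal atlas: straight 100-voxel strip plus two cubic labels
strip_atlas <- function() memo("strip100", {
  lab <- array(0L, dim = c(100, 5, 5))
  lab[, 3, 3] <- 1L
  lab[10:12, 1:2, 1:2] <- 2L
  lab[60:62, 1:2, 1:2] <- 3L
  label_atlas(lab, data.frame(
    label_id = 1:3, name = c("strip", "alpha", "beta"),
    hemisphere = c("M", "L", "L"),
    role = c("seed_roi", "target", "target")))
})

zone_target_names <- list(
  anterior = c("amygdala", "accumbens", "orbitofrontal", "insula"),
  mid = c("motor2", "caudoputamen", "parietal"),
  posterior = c("hippocampus", "hypothalamus"))

zone_voxels <- function(atlas) {
  lapply(zone_target_names, function(nm)
    atlas_voxels(atlas, atlas_labels(atlas, name = nm)))
}

# ICA support convention: within-structure voxels excluding the seed strip
ica_support <- function(atlas) {
  strip <- atlas_labels(atlas, role = "seed_roi")
  which(atlas$labels > 0L & !(atlas$labels %in% strip))
}

# standard 60-experiment phantom similarity map used by several ICA tests
phantom_similarity <- function() memo("sim60", {
  atl <- phantom_atlas()
  ex <- simulate_tracer_experiments(atl, default_tracer_rules("mouse", 0.2),
                                    60, rng_seed = 2, frac_off_strip = 0.25)
  sp <- place_seeds(atl, n_seeds = 20)
  projection_similarity(
    sample_density(ex, sp),
    sample_density(ex, brain_locations(atl, ica_support(atl))),
    seed_u = sp$u)
})

# naive double-loop Pearson, the micro-oracle
naive_pearson <- function(A, B) {
  out <- matrix(NA_real_, ncol(A), ncol(B))
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      x <- A[, i]; y <- B[, j]
      mx <- mean(x); my <- mean(y)
      num <- sum((x - mx) * (y - my))
      den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
      out[i, j] <- if (den == 0) NA_real_ else num / den
    }
  }
  out
}

# brute-force repeated-measures interaction F via stats::aov error strata
aov_interaction_F <- function(arr) {
  n <- dim(arr)[1]; a <- dim(arr)[2]; b <- dim(arr)[3]
  df <- data.frame(
    y = as.vector(arr),
    s = factor(rep(seq_len(n), a * b)),
    A = factor(rep(rep(seq_len(a), each = n), b)),
    B = factor(rep(seq_len(b), each = n * a)))
  sm <- summary(stats::aov(y ~ A * B + Error(s / (A * B)), data = df))
  sm[["Error: s:A:B"]][[1]]["A:B", "F value"]
}

# butterworth band-pass power gain after forward-backward filtering
filtfilt_gain <- function(low_hz, high_hz, fs, f) {
  flt <- signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  w <- 2 * pi * f / fs
  z <- exp(-1i * w * (seq_along(flt$b) - 1))
  H <- sum(flt$b * z) / sum(flt$a * exp(-1i * w * (seq_along(flt$a) - 1)))
  abs(H)^4
}

roi_ts <- function(x, tr_s = 1) {
  structure(list(values = matrix(x, nrow = 1), roi_ids = "x", tr_s = tr_s),
            class = "roi_timeseries")
}
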