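#' Extract mean ROI timeseries from a 4D scan
#'
#' @param scan a [scan4d].
#' @param rois list of voxel-index vectors (or a `seed_spec`).
#' @return An object of class `roi_timeseries`: `values` (ROIs x timepoints,
#'   unweighted voxel means), `roi_ids`, `tr_s`.
#' @export
extract_roi_timeseries <- function(scan, rois) {
  stopifnot(inherits(scan, "scan4d"))
  if (inherits(rois, "seed_spec")) rois <- rois$seeds
  if (!length(rois)) stopf("no ROIs")
  if (any(lengths(rois) == 0L)) stopf("empty ROI")
  nv <- nrow(scan$data)
  allv <- unlist(rois, use.names = FALSE)
  if (any(allv < 1L) || any(allv > nv)) stopf("ROI voxel outside grid")
  vals <- t(vapply(rois, function(v) {
    if (length(v) == 1L) scan$data[v, ] else colMeans(scan$data[v, , drop = FALSE])
  }, numeric(ncol(scan$data))))
  ids <- if (!is.null(names(rois))) names(rois) else seq_along(rois)
  structure(list(values = vals, roi_ids = ids, tr_s = scan$tr_s),
            class = "roi_timeseries")
}

#' Zero-phase Butterworth band-pass filter for ROI timeseries
#'
#' Each series is linearly detrended, then filtered with a 4th-order
#' Butterworth band-pass applied forward and backward (zero phase); output
#' length is unchanged. With `low_hz = 0` a low-pass is applied after
#' detrending.
#'
#' @param ts a [extract_roi_timeseries()] result.
#' @param low_hz,high_hz band edges in Hz; requires
#'   `0 <= low_hz < high_hz <= 1 / (2 * tr_s)`.
#' @return A filtered `roi_timeseries`.
#' @export
bandpass <- function(ts, low_hz, high_hz) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyq <- 1 / (2 * ts$tr_s)
  if (low_hz < 0 || low_hz >= high_hz)
    stopf("need 0 <= low_hz < high_hz")
  if (high_hz > nyq)
    stopf("high_hz (%g Hz) exceeds the Nyquist frequency (%g Hz)", high_hz,
          nyq)
  flt <- if (low_hz > 0)
    signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  else signal::butter(4, high_hz / nyq, type = "low")
  out <- ts
  out$values <- t(apply(ts$values, 1L, function(x)
    signal::filtfilt(flt, detrend_linear(x))))
  out
}

detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::lm.fit(cbind(1, t), x)$residuals
}

#' Per-subject seed-by-target functional connectivity
#'
#' @param ts a (filtered) `roi_timeseries` with >= 8 timepoints.
#' @param seed_rows,target_rows row indices of seeds and targets in `ts`.
#' @return seeds x targets matrix of Pearson correlations; a constant row
#'   yields `NA` entries with a warning.
#' @export
subject_fc <- function(ts, seed_rows, target_rows) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (ncol(ts$values) < 8L)
    stopf("need >= 8 timepoints, got %d", ncol(ts$values))
  S <- t(ts$values[seed_rows, , drop = FALSE])
  T_ <- t(ts$values[target_rows, , drop = FALSE])
  const_s <- apply(S, 2L, stats::sd) == 0
  const_t <- apply(T_, 2L, stats::sd) == 0
  if (any(const_s) || any(const_t))
    warnf("constant timeseries: correlations set to NA")
  r <- suppressWarnings(stats::cor(S, T_))
  r[const_s, ] <- NA_real_
  r[, const_t] <- NA_real_
  rownames(r) <- ts$roi_ids[seed_rows]
  colnames(r) <- ts$roi_ids[target_rows]
  r
}

#' Group connectivity fingerprint from per-subject matrices
#'
#' Averages raw correlations over subjects (arithmetic mean, matching the
#' convention of averaging r directly; set `fisher_z = TRUE` to average in
#' Fisher z space and back-transform the mean). `NA` cells are dropped
#' pairwise with a per-cell subject count; the SEM is the between-subject
#' sample standard deviation of raw r divided by `sqrt(n)` and is `NA`
#' where fewer than two subjects contribute.
#'
#' @param per_subject list of seeds x targets correlation matrices, one per
#'   subject, identical shapes.
#' @param seed_positions strictly increasing normalized seed positions.
#' @param species,modality tags for the fingerprint.
#' @param fisher_z average in Fisher z space (off by default).
#' @return A [fingerprint].
#' @export
group_fingerprint <- function(per_subject, seed_positions,
                              species = NA_character_, modality = "rsfmri",
                              fisher_z = FALSE) {
  if (!length(per_subject)) stopf("no subjects")
  d <- dim(per_subject[[1L]])
  for (m in per_subject)
    if (!all(dim(m) == d)) stopf("per-subject matrices differ in shape")
  arr <- array(unlist(per_subject), dim = c(d, length(per_subject)))
  n <- apply(!is.na(arr), c(1L, 2L), sum)
  if (fisher_z) {
    mean_r <- tanh(apply(atanh(arr), c(1L, 2L), mean, na.rm = TRUE))
  } else {
    mean_r <- apply(arr, c(1L, 2L), mean, na.rm = TRUE)
  }
  mean_r[n == 0L] <- NA_real_
  sdev <- apply(arr, c(1L, 2L), stats::sd, na.rm = TRUE)
  sem <- sdev / sqrt(n)
  sem[n < 2L] <- NA_real_
  colnames(mean_r) <- colnames(per_subject[[1L]])
  fingerprint(mean_r, sem, n, seed_positions = seed_positions,
              species = species, modality = modality)
}

#' Simulate a cohort and compute its group fingerprint in one pass
#'
#' Memory-lean driver used by the demo pipeline and validation suites: each
#' scan is generated, reduced to ROI timeseries, optionally band-passed and
#' correlated, then discarded. Optionally applies the functional-connectivity
#' specificity filter ([specificity_filter()]) and keeps only passing scans.
#'
#' @param atlas,model,n_subjects,n_timepoints,tr_s,rng_seed as in
#'   [simulate_rsfmri_scans()].
#' @param seed_spec a [place_seeds()] result.
#' @param target_sets named list of target voxel-index vectors.
#' @param band `c(low_hz, high_hz)` or `NULL` for no filtering.
#' @param qc list of QC arguments (`sensory`, `homotopic`, `dmn` voxel sets
#'   and optional `thr_pos`, `thr_neg`, `band`) or `NULL` to skip QC.
#' @param species tag for the fingerprint.
#' @return List with `fingerprint`, `per_subject` (correlation matrices of
#'   retained scans), `manifest` (subject_id, bad, qc pass if computed).
#' @export
cohort_fingerprint <- function(atlas, model, seed_spec, target_sets,
                               n_subjects, n_timepoints, tr_s = 1,
                               band = NULL, qc = NULL, rng_seed = 1L,
                               species = NA_character_) {
  stopifnot(inherits(seed_spec, "seed_spec"))
  prep <- bold_sim_prepare(atlas, model)
  rois <- c(seed_spec$seeds, target_sets)
  ns <- length(seed_spec$seeds)
  seed_rows <- seq_len(ns)
  target_rows <- ns + seq_along(target_sets)
  set.seed(as.integer(rng_seed))
  bad <- bad_scan_flags(model$frac_bad, n_subjects)
  per_subject <- vector("list", n_subjects)
  qc_rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    scan <- scan4d(bold_sim_draw(prep, n_timepoints, bad[s]),
                   grid_dim = dim(atlas$labels), tr_s = tr_s)
    keep <- TRUE
    if (!is.null(qc)) {
      qc_rep <- specificity_filter(scan, qc$sensory, qc$homotopic, qc$dmn,
                                   thr_pos = qc$thr_pos %||% 0.1,
                                   thr_neg = qc$thr_neg %||% 0.1,
                                   band = qc$band)
      qc_rep$scan_id <- s
      qc_rows[[s]] <- qc_rep
      keep <- qc_rep$pass
    }
    if (keep) {
      ts <- extract_roi_timeseries(scan, rois)
      if (!is.null(band)) ts <- bandpass(ts, band[1L], band[2L])
      m <- subject_fc(ts, seed_rows, target_rows)
      colnames(m) <- names(target_sets)
      per_subject[[s]] <- m
    }
  }
  manifest <- data.frame(subject_id = seq_len(n_subjects), bad = bad)
  if (!is.null(qc)) {
    qc_tab <- do.call(rbind, qc_rows)
    manifest$qc_pass <- qc_tab$pass
  }
  kept <- per_subject[!vapply(per_subject, is.null, logical(1L))]
  if (!length(kept)) stopf("no scans retained for the group fingerprint")
  fp <- group_fingerprint(kept, seed_positions = seed_spec$u,
                          species = species, modality = "rsfmri")
  out <- list(fingerprint = fp, per_subject = kept, manifest = manifest)
  if (!is.null(qc)) out$qc <- do.call(rbind, qc_rows)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
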