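#' Functional-connectivity specificity filter for one scan
#'
#' Scores a scan by two scalar criteria: `r_homotopic`, the Pearson
#' correlation between the mean timeseries of a sensory seed and its
#' homotopic contralateral seed, and `r_specificity`, the correlation
#' between the sensory seed and a default-mode seed. A scan passes when the
#' homotopic coupling is strong (`r_homotopic > thr_pos`) and the
#' sensory-default-mode coupling is absent or anticorrelated
#' (`r_specificity < thr_neg`); both inequalities are strict, so a
#' correlation exactly at a threshold fails. Seed series are linearly
#' detrended; pass `band` to additionally band-pass them, though note that
#' narrow-band filtering inflates the null sampling variance of r and makes
#' fixed thresholds less specific (see the methods vignette). A constant
#' seed series marks the scan as failed with reason `"degenerate"`.
#'
#' @param scan a [scan4d].
#' @param sensory_seed,homotopic_sensory_seed,dmn_seed disjoint voxel-index
#'   vectors.
#' @param thr_pos,thr_neg thresholds (defaults 0.1 and 0.1).
#' @param band optional `c(low_hz, high_hz)` band; `NULL` (default) for
#'   detrend-only.
#' @return One-row data.frame: `r_homotopic`, `r_specificity`, `pass`,
#'   `reason`; thresholds are attached as attributes `thr_pos`, `thr_neg`.
#' @export
specificity_filter <- function(scan, sensory_seed, homotopic_sensory_seed,
                               dmn_seed, thr_pos = 0.1, thr_neg = 0.1,
                               band = NULL) {
  stopifnot(inherits(scan, "scan4d"))
  seeds <- list(sensory = sensory_seed, homotopic = homotopic_sensory_seed,
                dmn = dmn_seed)
  if (anyDuplicated(unlist(seeds)))
    stopf("the three QC seed ROIs must be disjoint")
  ts <- extract_roi_timeseries(scan, seeds)
  degenerate <- any(apply(ts$values, 1L, stats::sd) == 0)
  ts$values <- t(apply(ts$values, 1L, detrend_linear))
  if (!is.null(band)) ts <- bandpass(ts, band[1L], band[2L])
  if (degenerate) {
    out <- data.frame(r_homotopic = NA_real_, r_specificity = NA_real_,
                      pass = FALSE, reason = "degenerate",
                      stringsAsFactors = FALSE)
  } else {
    r_h <- stats::cor(ts$values[1L, ], ts$values[2L, ])
    r_s <- stats::cor(ts$values[1L, ], ts$values[3L, ])
    out <- data.frame(r_homotopic = r_h, r_specificity = r_s,
                      pass = r_h > thr_pos && r_s < thr_neg, reason = "",
                      stringsAsFactors = FALSE)
  }
  attr(out, "thr_pos") <- thr_pos
  attr(out, "thr_neg") <- thr_neg
  out
}

#' Apply the specificity filter to a whole cohort
#'
#' @param scans list of [scan4d] (e.g. from [simulate_rsfmri_scans()]).
#' @param ... arguments passed to [specificity_filter()].
#' @return data.frame with one row per scan (`scan_id`, `r_homotopic`,
#'   `r_specificity`, `pass`, `reason`).
#' @export
qc_cohort <- function(scans, ...) {
  rows <- lapply(seq_along(scans), function(i) {
    r <- specificity_filter(scans[[i]], ...)
    cbind(scan_id = i, r)
  })
  do.call(rbind, rows)
}

#' Restrict a scan manifest to QC-passing scans
#'
#' @param manifest data.frame with a `scan_id` column (or `subject_id`,
#'   used as scan id).
#' @param reports QC report data.frame covering exactly the manifest's
#'   scans (columns `scan_id`, `pass`).
#' @return The manifest rows whose scans passed, in the original order.
#'   Warns (without erroring) when nothing passes.
#' @export
filter_manifest <- function(manifest, reports) {
  id_col <- if ("scan_id" %in% names(manifest)) "scan_id" else "subject_id"
  if (!id_col %in% names(manifest))
    stopf("manifest needs a scan_id or subject_id column")
  if (!all(c("scan_id", "pass") %in% names(reports)))
    stopf("reports need scan_id and pass columns")
  ids <- manifest[[id_col]]
  if (!setequal(ids, reports$scan_id) || length(ids) != nrow(reports))
    stopf("QC reports do not match the manifest (%d scans vs %d reports)",
          length(ids), nrow(reports))
  pass <- reports$pass[match(ids, reports$scan_id)]
  message(sprintf("QC: %d of %d scans retained", sum(pass), length(pass)))
  if (!any(pass)) warnf("no scans passed QC; returning an empty manifest")
  manifest[pass, , drop = FALSE]
}

#' Simulate a scan cohort and score it with the specificity filter
#'
#' Memory-lean driver for operating-characteristic studies: each scan is
#' generated from the BOLD model (a `frac_bad` fraction as pure noise),
#' scored with [specificity_filter()], and discarded. The generator truth
#' is returned alongside the QC decision.
#'
#' @param atlas,model,n_scans,n_timepoints,tr_s,rng_seed as in
#'   [simulate_rsfmri_scans()].
#' @param sensory_seed,homotopic_sensory_seed,dmn_seed,thr_pos,thr_neg,band
#'   as in [specificity_filter()].
#' @return data.frame with columns `scan_id`, `bad` (generator truth),
#'   `r_homotopic`, `r_specificity`, `pass`, `reason`.
#' @export
simulate_qc_cohort <- function(atlas, model, n_scans, n_timepoints,
                               tr_s = 1, rng_seed = 1L, sensory_seed,
                               homotopic_sensory_seed, dmn_seed,
                               thr_pos = 0.1, thr_neg = 0.1, band = NULL) {
  prep <- bold_sim_prepare(atlas, model)
  set.seed(as.integer(rng_seed))
  bad <- bad_scan_flags(model$frac_bad, n_scans)
  rows <- vector("list", n_scans)
  for (s in seq_len(n_scans)) {
    scan <- scan4d(bold_sim_draw(prep, n_timepoints, bad[s]),
                   grid_dim = dim(atlas$labels), tr_s = tr_s)
    r <- specificity_filter(scan, sensory_seed, homotopic_sensory_seed,
                            dmn_seed, thr_pos = thr_pos, thr_neg = thr_neg,
                            band = band)
    rows[[s]] <- cbind(scan_id = s, bad = bad[s], r)
  }
  do.call(rbind, rows)
}
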