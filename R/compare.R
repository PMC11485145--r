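#' Align two fingerprints on a common rostro-caudal grid
#'
#' Pairs homologous targets across the two fingerprints and linearly
#' interpolates each target's profile over seeds onto `m` evenly spaced
#' normalized positions within the overlap of the two seed ranges. No
#' warping of the axis is applied: the premise is positional correspondence
#' of the rostro-caudal gradient across species.
#'
#' @param fpA,fpB [fingerprint]s with >= 2 seeds each.
#' @param homolog_map data.frame with columns `name_a`, `name_b` pairing
#'   target names of `fpA` with those of `fpB`; defaults to the identity
#'   map on the shared target names.
#' @param m number of grid points (default: the larger seed count).
#' @return Object of class `aligned_fingerprints`: `u` (common grid),
#'   `A`, `B` (m x targets matrices, identical column order), `targets`
#'   (the homolog map).
#' @export
align_fingerprints <- function(fpA, fpB, homolog_map = NULL, m = NULL) {
  stopifnot(inherits(fpA, "fingerprint"), inherits(fpB, "fingerprint"))
  if (nrow(fpA$mean_r) < 2L || nrow(fpB$mean_r) < 2L)
    stopf("both fingerprints need >= 2 seeds to interpolate")
  if (is.null(homolog_map)) {
    shared <- intersect(colnames(fpA$mean_r), colnames(fpB$mean_r))
    if (!length(shared)) stopf("no shared target names and no homolog_map")
    homolog_map <- data.frame(name_a = shared, name_b = shared,
                              stringsAsFactors = FALSE)
  }
  miss_a <- setdiff(homolog_map$name_a, colnames(fpA$mean_r))
  miss_b <- setdiff(homolog_map$name_b, colnames(fpB$mean_r))
  if (length(miss_a) || length(miss_b))
    stopf("unmatched target name(s): %s",
          paste(c(miss_a, miss_b), collapse = ", "))
  lo <- max(min(fpA$seed_positions), min(fpB$seed_positions))
  hi <- min(max(fpA$seed_positions), max(fpB$seed_positions))
  if (lo >= hi) stopf("seed position ranges do not overlap")
  if (is.null(m)) m <- max(nrow(fpA$mean_r), nrow(fpB$mean_r))
  u <- seq(lo, hi, length.out = m)
  interp <- function(fp, cols) {
    vapply(cols, function(cn)
      stats::approx(fp$seed_positions, fp$mean_r[, cn], xout = u)$y,
      numeric(m))
  }
  A <- interp(fpA, homolog_map$name_a)
  B <- interp(fpB, homolog_map$name_b)
  colnames(A) <- colnames(B) <- homolog_map$name_a
  structure(list(u = u, A = A, B = B, targets = homolog_map),
            class = "aligned_fingerprints")
}

#' Quantify similarity of two aligned fingerprints
#'
#' Per-target scores are the Pearson correlation between the two profiles
#' over the common grid (`NA` with a warning for a constant profile).
#' Overall scores: `pearson_per_target` reports the mean of the per-target
#' correlations, `cosine_overall` the cosine similarity of the flattened
#' matrices, `manhattan_overall` the mean absolute difference.
#'
#' @param pair an [align_fingerprints()] result.
#' @param metric one or more of `"pearson_per_target"`, `"cosine_overall"`,
#'   `"manhattan_overall"` (default: all three).
#' @return Object of class `fingerprint_similarity`: `per_target` (named
#'   per-target Pearson r) and `overall` (named vector of the requested
#'   overall scores).
#' @export
fingerprint_similarity <- function(pair,
                                   metric = c("pearson_per_target",
                                              "cosine_overall",
                                              "manhattan_overall")) {
  stopifnot(inherits(pair, "aligned_fingerprints"))
  metric <- match.arg(metric, several.ok = TRUE)
  per_target <- vapply(seq_len(ncol(pair$A)), function(j) {
    r <- pearson_safe(pair$A[, j], pair$B[, j])
    r
  }, numeric(1L))
  names(per_target) <- colnames(pair$A)
  if (anyNA(per_target))
    warnf("constant profile(s): per-target correlation NA for %s",
          paste(names(per_target)[is.na(per_target)], collapse = ", "))
  a <- as.vector(pair$A); b <- as.vector(pair$B)
  overall <- c(
    pearson_per_target = mean(per_target, na.rm = TRUE),
    cosine_overall = sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
    manhattan_overall = mean(abs(a - b)))[metric]
  structure(list(per_target = per_target, overall = overall),
            class = "fingerprint_similarity")
}

#' @export
print.fingerprint_similarity <- function(x, ...) {
  cat("<fingerprint_similarity>\nper-target Pearson r:\n")
  print(round(x$per_target, 3))
  cat("overall:\n")
  print(round(x$overall, 4))
  invisible(x)
}
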