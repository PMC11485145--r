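#' Connectivity fingerprint container
#'
#' A seeds-by-targets matrix of mean connectivity values with, for group
#' (fMRI) fingerprints, the between-subject SEM and per-cell subject counts.
#' The seeds are ordered along the rostro-caudal axis by their normalized
#' position `u` in `[0, 1]`. Fingerprints are the common currency for
#' cross-modality and cross-species comparison.
#'
#' @param mean_r seeds x targets numeric matrix; column names are target
#'   names.
#' @param sem matching matrix of standard errors of the mean (`NA` where
#'   fewer than 2 subjects contributed).
#' @param n per-cell number of subjects (matrix or scalar).
#' @param seed_positions ascending numeric vector of normalized seed
#'   positions, one per row.
#' @param species,modality free-text tags (e.g. `"mouse"`, `"tracer"`).
#' @return An object of class `fingerprint`.
#' @export
fingerprint <- function(mean_r, sem = NULL, n = 1L, seed_positions,
                        species = NA_character_, modality = NA_character_) {
  mean_r <- as.matrix(mean_r)
  if (is.null(colnames(mean_r)))
    colnames(mean_r) <- paste0("target", seq_len(ncol(mean_r)))
  if (is.null(sem)) sem <- matrix(NA_real_, nrow(mean_r), ncol(mean_r))
  sem <- as.matrix(sem)
  if (!all(dim(sem) == dim(mean_r))) stopf("sem shape must match mean_r")
  if (any(sem < 0, na.rm = TRUE)) stopf("sem must be non-negative")
  if (any(abs(mean_r) > 1 + 1e-12, na.rm = TRUE))
    stopf("|mean_r| must be <= 1")
  if (length(n) == 1L) n <- matrix(n, nrow(mean_r), ncol(mean_r))
  n <- as.matrix(n)
  seed_positions <- as.numeric(seed_positions)
  if (length(seed_positions) != nrow(mean_r))
    stopf("need one seed position per fingerprint row")
  if (is.unsorted(seed_positions, strictly = TRUE))
    stopf("seed_positions must be strictly increasing")
  dimnames(sem) <- dimnames(n) <- dimnames(mean_r)
  structure(list(mean_r = mean_r, sem = sem, n = n,
                 seed_positions = seed_positions,
                 species = species, modality = modality),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, digits = 3, ...) {
  cat(sprintf("<fingerprint> %d seeds x %d targets (%s, %s), n = %s\n",
              nrow(x$mean_r), ncol(x$mean_r),
              ifelse(is.na(x$species), "?", x$species),
              ifelse(is.na(x$modality), "?", x$modality),
              paste(range(x$n), collapse = "-")))
  print(round(x$mean_r, digits))
  invisible(x)
}

#' @export
plot.fingerprint <- function(x, targets = colnames(x$mean_r), ...) {
  nt <- length(targets)
  nc <- ceiling(sqrt(nt))
  op <- graphics::par(mfrow = c(ceiling(nt / nc), nc), mar = c(2, 3, 2, 0.5))
  on.exit(graphics::par(op))
  for (t in targets) {
    m <- x$mean_r[, t]
    s <- x$sem[, t]
    ylim <- range(0, m - s, m + s, na.rm = TRUE)
    bp <- graphics::barplot(m, names.arg = seq_along(m), ylim = ylim,
                            main = t, ...)
    ok <- !is.na(s) & s > 0
    if (any(ok))
      graphics::arrows(bp[ok], (m - s)[ok], bp[ok], (m + s)[ok],
                       angle = 90, code = 3, length = 0.02)
  }
  invisible(x)
}

#' Write a fingerprint as a long-format TSV
#'
#' One row per (seed, target) cell with columns `seed_index`,
#' `seed_position`, `target_name`, `mean_r`, `sem`, `n_subjects`. Missing
#' values are written as the literal token `NA`. Values round-trip through
#' [read_fingerprint_table()] to full stored precision.
#'
#' @param fp a [fingerprint].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_table <- function(fp, path) {
  stopifnot(inherits(fp, "fingerprint"))
  s <- nrow(fp$mean_r); t <- ncol(fp$mean_r)
  long <- data.frame(
    seed_index = rep(seq_len(s), times = t),
    seed_position = rep(fp$seed_positions, times = t),
    target_name = rep(colnames(fp$mean_r), each = s),
    mean_r = as.vector(fp$mean_r),
    sem = as.vector(fp$sem),
    n_subjects = as.vector(fp$n),
    stringsAsFactors = FALSE)
  num <- vapply(long, is.double, logical(1L))
  long[num] <- lapply(long[num], function(v)
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v)))
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot open %s for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a fingerprint written by [write_fingerprint_table()]
#'
#' @param path TSV path.
#' @param species,modality tags to attach.
#' @return A [fingerprint].
#' @export
read_fingerprint_table <- function(path, species = NA_character_,
                                   modality = NA_character_) {
  long <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     na.strings = "NA")
  need <- c("seed_index", "seed_position", "target_name", "mean_r", "sem",
            "n_subjects")
  if (!all(need %in% names(long)))
    stopf("%s is not a fingerprint table", path)
  seeds <- sort(unique(long$seed_index))
  targets <- unique(long$target_name)
  shape <- list(seed = seeds, target = targets)
  grab <- function(col) {
    m <- matrix(NA_real_, length(seeds), length(targets), dimnames = shape)
    m[cbind(match(long$seed_index, seeds),
            match(long$target_name, targets))] <- long[[col]]
    dimnames(m) <- list(NULL, targets)
    m
  }
  u <- long$seed_position[match(seeds, long$seed_index)]
  fingerprint(grab("mean_r"), grab("sem"), grab("n_subjects"),
              seed_positions = u, species = species, modality = modality)
}
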