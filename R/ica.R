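# Fixed-point ICA with logcosh contrast and symmetric decorrelation.
# X: mixtures x samples, rows already centred. Non-convergent starts are
# retried from fresh random rotations (deterministic given the RNG state);
# only when every restart stalls is a convergence error raised, carrying
# the iteration count. Returns list(S, A, iters): S k x samples
# (unit-variance sources), A mixtures x k (mixing weights).
fastica_logcosh <- function(X, k, tol = 1e-6, max_iter = 500L,
                            n_restarts = 4L) {
  p <- nrow(X); n <- ncol(X)
  C <- tcrossprod(X) / n
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[k] <= .Machine$double.eps * eg$values[1L])
    stopf("data rank below %d components", k)
  K <- diag(1 / sqrt(eg$values[seq_len(k)]), k) %*%
    t(eg$vectors[, seq_len(k), drop = FALSE])      # whitening, k x p
  Z <- K %*% X                                     # k x n, white
  tZn <- t(Z) / n
  for (start in seq_len(n_restarts + 1L)) {
    W <- sym_decorrelate(matrix(stats::rnorm(k * k), k, k))
    it <- 0L
    delta <- Inf
    while (it < max_iter) {
      it <- it + 1L
      U <- W %*% Z
      G <- tanh(U)
      W_new <- sym_decorrelate(G %*% tZn - diag(rowMeans(1 - G^2), k) %*% W)
      delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
      W <- W_new
      if (delta < tol) break
    }
    if (delta < tol) {
      S <- W %*% Z
      A <- X %*% t(S) / n      # unit-variance orthogonal sources
      return(list(S = S, A = A, iters = it))
    }
  }
  stopf("ICA did not converge after %d iterations x %d starts (delta %.2e)",
        max_iter, n_restarts + 1L, delta)
}

sym_decorrelate <- function(W) {
  sv <- La.svd(W)
  sv$u %*% sv$vt
}

#' Decompose a similarity map into spatial independent components
#'
#' Runs spatial ICA on the seeds-by-voxels similarity matrix: columns with
#' undefined entries are dropped from the support, each seed row is centred,
#' the data are reduced by PCA to `n_components` and unmixed by fixed-point
#' ICA with the logcosh contrast and symmetric decorrelation (tolerance
#' 1e-6, at most 500 iterations). Each component is a z-scaled spatial map
#' over voxels (voxels with similar correlations to the cingulate seeds)
#' plus a weight per seed. Maps are sign-flipped so their skewness is
#' positive (tie: the largest-magnitude voxel is made positive) and ordered
#' by explained variance, descending. Deterministic given `rng_seed`.
#'
#' @param sim a [projection_similarity()] map.
#' @param n_components number of components, at most `min(seeds, defined
#'   voxels)`.
#' @param rng_seed integer seed for the unmixing initialisation.
#' @return An object of class `component_solution`: `spatial_maps`
#'   (n_components x support voxels, zero mean unit variance rows),
#'   `seed_weights` (seeds x n_components), `seed_assignment`,
#'   `var_explained`, `support` (voxel indices of the map columns),
#'   `seed_u`, `iters`.
#' @export
decompose <- function(sim, n_components, rng_seed = 1L) {
  stopifnot(inherits(sim, "similarity_map"), is_count(n_components),
            n_components >= 1)
  defined <- colSums(is.na(sim$values)) == 0L
  X <- sim$values[, defined, drop = FALSE]
  if (n_components > min(nrow(X), ncol(X)))
    stopf("n_components (%d) exceeds min(seeds, defined voxels) = %d",
          n_components, min(nrow(X), ncol(X)))
  # melodic-style spatial ICA: centre each voxel column across seeds
  X <- sweep(X, 2L, colMeans(X))
  set.seed(as.integer(rng_seed))
  fit <- fastica_logcosh(X, n_components)
  S <- fit$S; A <- fit$A
  # z-scale maps exactly (sample moments over voxels)
  mu <- rowMeans(S)
  sdev <- sqrt(rowSums((S - mu)^2) / (ncol(S) - 1L))
  S <- (S - mu) / sdev
  A <- A * rep(sdev, each = nrow(A))
  # sign convention
  for (i in seq_len(nrow(S))) {
    sk <- mean(S[i, ]^3)
    flip <- if (abs(sk) > 1e-12) sk < 0 else S[i, which.max(abs(S[i, ]))] < 0
    if (flip) {
      S[i, ] <- -S[i, ]
      A[, i] <- -A[, i]
      mu[i] <- -mu[i]
    }
  }
  ve <- colSums(A^2)
  ord <- order(ve, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  ve <- ve[ord]
  support <- unlist(sim$voxels, use.names = FALSE)[defined]
  sol <- structure(list(spatial_maps = S, seed_weights = A,
                        var_explained = ve, support = support,
                        map_mean = mu[ord], map_sd = sdev[ord],
                        seed_u = sim$seed_u, iters = fit$iters),
                   class = "component_solution")
  sol$seed_assignment <- assign_seeds(sol)
  sol
}

#' @export
print.component_solution <- function(x, ...) {
  cat(sprintf(
    "<component_solution> %d components over %d voxels, %d seeds (%d iters)\n",
    nrow(x$spatial_maps), ncol(x$spatial_maps), nrow(x$seed_weights),
    x$iters))
  cat("seeds per component:",
      paste(tabulate(x$seed_assignment, nrow(x$spatial_maps)),
            collapse = " "), "\n")
  invisible(x)
}

#' Assign each seed to its dominant component
#'
#' Threshold-free assignment: each seed goes to the component it expresses
#' most strongly. Because spatial maps are oriented positive (skewness
#' convention), a positive seed weight means the seed's connectivity
#' resembles the map while a negative weight means it anti-resembles it, so
#' the default takes the largest signed weight. Set `signed = FALSE` to use
#' the largest absolute weight instead. Ties break to the lower component
#' index.
#'
#' @param solution a [decompose()] result.
#' @param signed use signed (default) rather than absolute weights.
#' @return Integer vector, one component index per seed.
#' @export
assign_seeds <- function(solution, signed = TRUE) {
  stopifnot(inherits(solution, "component_solution"))
  w <- solution$seed_weights
  if (!signed) w <- abs(w)
  apply(w, 1L, which.max)
}

#' Decompose at several component orders and match components across them
#'
#' @param sim a similarity map.
#' @param orders integer vector of component counts (e.g. `4:9`).
#' @param rng_seed integer seed, used for every order.
#' @return List of class `order_sweep`: `solutions` (one per order, named by
#'   order) and `matching`, a data.frame pairing components of consecutive
#'   orders by greedy maximal absolute spatial correlation (columns
#'   order_a, component_a, order_b, component_b, r).
#' @export
order_sweep <- function(sim, orders, rng_seed = 1L) {
  stopifnot(length(orders) >= 1)
  orders <- as.integer(orders)
  solutions <- lapply(orders, function(k) decompose(sim, k, rng_seed))
  names(solutions) <- as.character(orders)
  rows <- list()
  if (length(orders) > 1L) {
    for (t in seq_len(length(orders) - 1L)) {
      R <- stats::cor(t(solutions[[t]]$spatial_maps),
                      t(solutions[[t + 1L]]$spatial_maps))
      M <- abs(R)
      while (any(is.finite(M))) {
        ij <- arrayInd(which.max(M), dim(M))
        rows[[length(rows) + 1L]] <- data.frame(
          order_a = orders[t], component_a = ij[1L],
          order_b = orders[t + 1L], component_b = ij[2L],
          r = R[ij[1L], ij[2L]])
        M[ij[1L], ] <- -Inf
        M[, ij[2L]] <- -Inf
      }
    }
  }
  matching <- if (length(rows)) do.call(rbind, rows)
  else data.frame(order_a = integer(), component_a = integer(),
                  order_b = integer(), component_b = integer(),
                  r = numeric())
  structure(list(solutions = solutions, matching = matching),
            class = "order_sweep")
}
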