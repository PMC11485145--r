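test_that("seeds fall at rank quantiles along the rostro-caudal axis", {
  atl <- strip_atlas()
  sp <- place_seeds(atl, roi_label_ids = 1L, n_seeds = 10)
  # straight 100-voxel strip: seeds at 1-based ranks 5, 15, ..., 95
  strip_vox <- atlas_voxels(atl, 1L)
  ranked <- strip_vox[order(cingfp:::vox_coords(strip_vox,
                                                dim(atl$labels))[, 1])]
  expect_equal(unlist(sp$seeds), ranked[seq(5, 95, by = 10)])
  expect_equal(sp$u, seq(0.05, 0.95, by = 0.1))

  all_sp <- place_seeds(atl, 1L, n_seeds = 100)
  expect_setequal(unlist(all_sp$seeds), strip_vox)
  one <- place_seeds(atl, 1L, n_seeds = 1)
  expect_equal(unlist(one$seeds), ranked[50])
  expect_error(place_seeds(atl, 1L, n_seeds = 101), "exceeds")
})

test_that("density sampling averages over location voxels", {
  d1 <- array(0, c(100, 5, 5)); d1[10, 1, 1] <- 1; d1[60, 1, 1] <- 3
  d2 <- array(0, c(100, 5, 5))
  pm <- sample_density(list(d1, d2),
                       list(a = which(d1 == 1),
                            b = c(which(d1 == 1), which(d1 == 3)),
                            c = 5L))
  expect_equal(pm[1, ], c(a = 1, b = 2, c = 0))   # single voxel / mean / zero
  expect_equal(unname(pm[2, ]), c(0, 0, 0))       # all-zero experiment
  expect_error(sample_density(list(d1), list(integer(0))), "empty")
})

test_that("projection similarity is Pearson across experiments with NA for
           constant columns", {
  seed <- matrix(c(1, 2, 3, 4), ncol = 1)
  brain <- cbind(v1 = c(1, 2, 3, 4), v2 = c(9, 8, 7, 6), v3 = c(1, 3, 2, 4),
                 v4 = rep(2, 4))
  sim <- projection_similarity(seed, brain)
  expect_equal(unname(sim$values[1, "v1"]), 1)
  expect_equal(unname(sim$values[1, "v2"]), -1)  # negated and shifted seed
  expect_equal(unname(sim$values[1, "v3"]), 0.8)
  expect_true(is.na(sim$values[1, "v4"]))
  expect_error(projection_similarity(seed[1:2, , drop = FALSE],
                                     brain[1:2, ]), ">= 3 experiments")
})

test_that("projection similarity matches the double-loop Pearson oracle", {
  set.seed(4)
  A <- matrix(rnorm(5 * 4), 5, 4)
  B <- matrix(rnorm(5 * 20), 5, 20)
  sim <- projection_similarity(A, B)
  expect_lt(max(abs(sim$values - naive_pearson(A, B))), 1e-10)
})

test_that("similarity is invariant to positive affine rescaling of a
           location's densities", {
  set.seed(5)
  A <- matrix(runif(6 * 3), 6, 3)
  B <- matrix(runif(6 * 8), 6, 8)
  r1 <- projection_similarity(A, B)$values
  B2 <- B; B2[, 5] <- 3.7 * B2[, 5] + 0.4
  r2 <- projection_similarity(A, B2)$values
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_true(all(abs(r1) <= 1, na.rm = TRUE))
})

test_that("tracer fingerprints recover the planted rostro-caudal gradient", {
  atl <- phantom_atlas()
  ex <- simulate_tracer_experiments(atl, default_tracer_rules("mouse", 0.2),
                                    60, rng_seed = 2, frac_off_strip = 0.25)
  sp10 <- place_seeds(atl, n_seeds = 10)
  targets <- target_rois(atl)
  bd <- sample_density(ex, brain_locations(atl))
  sim_s <- projection_similarity(sample_density(ex, sp10), bd,
                                 seed_u = sp10$u)
  sim_t <- projection_similarity(sample_density(ex, targets), bd)
  excl <- c(atlas_voxels(atl, atlas_labels(atl, role = "seed_roi")),
            unlist(targets))
  fp <- tracer_fingerprint(sim_s, sim_t, excl, target_names = names(targets),
                           species = "mouse")
  expect_true(all(is.na(fp$sem)))
  # most anterior seed peaks at a limbic-zone target
  expect_true(colnames(fp$mean_r)[which.max(fp$mean_r[1, ])] %in%
                zone_target_names$anterior)
  # mid seed peaks at a motor/striatal-zone target
  expect_true(colnames(fp$mean_r)[which.max(fp$mean_r[5, ])] %in%
                zone_target_names$mid)
  # rows group by planted zone: within-zone cosine exceeds across-zone
  zone <- cut(sp10$u, c(0, 1/3, 2/3, 1), labels = FALSE)
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  cs <- outer(seq_len(10), seq_len(10), Vectorize(function(i, j)
    cosine(fp$mean_r[i, ], fp$mean_r[j, ])))
  same <- outer(zone, zone, "==") & upper.tri(cs)
  diff <- outer(zone, zone, "!=") & upper.tri(cs)
  expect_gt(mean(cs[same]), mean(cs[diff]))
})

test_that("identical similarity rows give a unit fingerprint entry and
           self-voxel exclusion equalises twin targets", {
  vox <- as.list(1:40)
  vals <- matrix(rnorm(2 * 40), 2, 40)
  mk_map <- function(v) structure(list(values = v, voxels = vox,
                                       seed_u = NULL),
                                  class = "similarity_map")
  sim_s <- mk_map(vals)
  sim_s$seed_u <- c(0.25, 0.75)
  # target 1 = seed row 1; targets 2 and 3 differ only at their own voxels
  tv <- vals[c(1, 2, 2), ]
  tv[2, 39] <- 5; tv[3, 40] <- -5
  sim_t <- mk_map(tv)
  fp_all <- tracer_fingerprint(sim_s, sim_t, exclude_voxels = integer(0),
                               seed_positions = sim_s$seed_u)
  fp_ex <- tracer_fingerprint(sim_s, sim_t, exclude_voxels = 39:40,
                              seed_positions = sim_s$seed_u)
  expect_equal(unname(fp_ex$mean_r[1, 1]), 1)
  expect_false(isTRUE(all.equal(fp_all$mean_r[, 2], fp_all$mean_r[, 3])))
  expect_equal(unname(fp_ex$mean_r[, 2]), unname(fp_ex$mean_r[, 3]),
               tolerance = 1e-12)
  expect_error(tracer_fingerprint(sim_s, sim_t, exclude_voxels = 1:35,
                                  seed_positions = sim_s$seed_u),
               "fewer than 10")
})
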