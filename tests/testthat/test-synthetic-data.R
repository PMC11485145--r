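test_that("phantom atlas has the promised label inventory", {
  atl <- phantom_atlas()
  tab <- atl$table
  expect_equal(sum(tab$role == "seed_roi"), 1L)
  expect_equal(sum(tab$role == "target"), 18L)  # 9 bilateral pairs
  expect_equal(sum(tab$role == "sensory"), 2L)
  expect_equal(sum(tab$role == "dmn"), 1L)
  # strip spans >= 80% of the rostro-caudal extent
  strip <- atlas_voxels(atl, atlas_labels(atl, role = "seed_roi"))
  ri <- range(cingfp:::vox_coords(strip, dim(atl$labels))[, 1])
  expect_gte(diff(ri) + 1, 0.8 * dim(atl$labels)[1])
  # labels disjoint by construction: every non-zero voxel appears once
  expect_true(all(tabulate(atl$labels[atl$labels > 0]) > 0))
})

test_that("phantom atlas is deterministic in its seed and supports n_targets = 0", {
  a1 <- build_phantom_atlas(c(20, 24, 14), rng_seed = 7)
  a2 <- build_phantom_atlas(c(20, 24, 14), rng_seed = 7)
  expect_identical(a1$labels, a2$labels)
  expect_identical(a1$table, a2$table)
  a0 <- build_phantom_atlas(c(20, 24, 14), n_targets = 0)
  expect_equal(sum(a0$table$role == "target"), 0L)
  expect_equal(sum(a0$table$role == "seed_roi"), 1L)
  expect_error(build_phantom_atlas(c(8, 8, 8), n_targets = 40), "overlap")
})

test_that("tracer generator honours the zone response in closed form", {
  atl <- phantom_atlas()
  # single-zone rule set: amygdala wired, motor2 in no zone
  base <- tracer_ruleset(list(tracer_zone(0.5, 0.1, "amygdala",
                                          strength = 1.5)),
                         background_density = 0.07, noise_sd = 0)
  ex <- simulate_tracer_experiments(atl, base, 1, rng_seed = 3)
  motor_vox <- atlas_voxels(atl, atlas_labels(atl, name = "motor2"))
  expect_equal(unique(ex[[1]]$density[motor_vox]), 0.07)
  # re-centre the zone exactly on the realized injection position:
  # density in the zone target is then strength + background exactly
  u0 <- ex[[1]]$injection_u
  rules2 <- tracer_ruleset(list(tracer_zone(u0, 0.1, "amygdala",
                                            strength = 1.5)),
                           background_density = 0.07, noise_sd = 0)
  ex2 <- simulate_tracer_experiments(atl, rules2, 1, rng_seed = 3)
  amy_vox <- atlas_voxels(atl, atlas_labels(atl, name = "amygdala"))
  expect_equal(unique(ex2[[1]]$density[amy_vox]), 1.5 + 0.07)
})

test_that("tracer collections are non-negative and deterministic per seed", {
  atl <- phantom_atlas()
  rules <- default_tracer_rules("mouse", 0.2)
  ex <- simulate_tracer_experiments(atl, rules, 50, rng_seed = 11)
  expect_length(ex, 50L)
  expect_true(all(vapply(ex, function(e) min(e$density) >= 0, logical(1))))
  ex2 <- simulate_tracer_experiments(atl, rules, 50, rng_seed = 11)
  expect_identical(ex[[17]]$density, ex2[[17]]$density)
  expect_error(
    simulate_tracer_experiments(
      atl, tracer_ruleset(list(tracer_zone(0.5, 0.1, "thalamus"))), 5),
    "unknown target")
})

test_that("narrowing a zone strictly reduces density reaching its targets
           from injections outside the zone width", {
  atl <- phantom_atlas()
  amy <- atlas_voxels(atl, atlas_labels(atl, name = "amygdala"))
  dens_at <- function(w) {
    rules <- tracer_ruleset(list(tracer_zone(0.1, w, "amygdala")),
                            background_density = 0, noise_sd = 0)
    ex <- simulate_tracer_experiments(atl, rules, 9, rng_seed = 5)
    # pick experiments injected well outside u_center +- w
    far <- vapply(ex, function(e) abs(e$injection_u - 0.1) > 0.3, logical(1))
    vapply(ex[far], function(e) mean(e$density[amy]), numeric(1))
  }
  wide <- dens_at(0.2)
  narrow <- dens_at(0.1)
  expect_true(all(narrow < wide))
})

test_that("planted BOLD covariance matches the block model", {
  # two voxels sharing a latent: population r = s^2 / (s^2 + sigma^2)
  lab <- array(0L, c(4, 4, 4))
  lab[1, 1, 1] <- 1L; lab[2, 2, 2] <- 2L; lab[3, 3, 3] <- 3L
  atl <- label_atlas(lab, data.frame(
    label_id = 1:3, name = c("net_a", "net_a2", "net_b"),
    hemisphere = c("L", "R", "M"),
    role = c("target", "target", "dmn")))
  model <- bold_model(
    data.frame(label_id = 1:3, network = c("a", "a", "b")),
    signal_sd = c(a = 1, b = 1), noise_sd = 1,
    anticorrelated_pairs = list(c("a", "b")))
  scans <- simulate_rsfmri_scans(atl, model, 1, 2000, tr_s = 1,
                                 rng_seed = 21)
  x <- scans[[1]]$data
  v <- c(which(lab == 1L), which(lab == 2L), which(lab == 3L))
  r_same <- cor(x[v[1], ], x[v[2], ])
  expect_gte(r_same, 0.45)  # closed form 0.5
  expect_lte(r_same, 0.55)
  # anticorrelated networks: population r = -0.5 here
  r_anti <- cor(x[v[1], ], x[v[3], ])
  expect_lt(abs(r_anti + 0.5), 3 / sqrt(2000) + 0.05)
  # near-noiseless limit drives the anticorrelation to -1
  m0 <- bold_model(model$assignment, signal_sd = c(a = 1, b = 1),
                   noise_sd = 1e-6,
                   anticorrelated_pairs = list(c("a", "b")))
  s0 <- simulate_rsfmri_scans(atl, m0, 1, 100, rng_seed = 3)
  expect_equal(cor(s0[[1]]$data[v[1], ], s0[[1]]$data[v[3], ]), -1,
               tolerance = 1e-6)
})

test_that("bad-scan flags and determinism behave as configured", {
  atl <- qc_atlas()
  model <- default_bold_model(atl, "mouse", frac_bad = 1)
  scans <- simulate_rsfmri_scans(atl, model, 4, 32, rng_seed = 1)
  expect_true(all(vapply(scans, `[[`, logical(1), "bad")))
  expect_true(all(attr(scans, "manifest")$bad))
  m2 <- default_bold_model(atl, "mouse")
  s1 <- simulate_rsfmri_scans(atl, m2, 2, 32, rng_seed = 9)
  s2 <- simulate_rsfmri_scans(atl, m2, 2, 32, rng_seed = 9)
  expect_identical(s1[[2]]$data, s2[[2]]$data)
  expect_error(simulate_rsfmri_scans(atl, m2, 2, 8), ">= 16")
})

test_that("unassigned target labels are a configuration error", {
  atl <- qc_atlas()
  model <- default_bold_model(atl, "mouse")
  model$assignment <- model$assignment[model$assignment$network != "posterior" |
                                         !is.na(model$assignment$u_min), ]
  expect_error(simulate_rsfmri_scans(atl, model, 1, 32), "not assigned")
})
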