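test_that("integer volumes round-trip bit-exactly through NIfTI", {
  arr <- array(sample.int(100, 64, replace = TRUE), dim = c(4, 4, 4))
  vol <- volume_grid(arr, voxel_size_mm = c(0.2, 0.2, 0.4))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(array(as.integer(back$data), dim(arr)), arr)
  expect_equal(back$voxel_size_mm, c(0.2, 0.2, 0.4), tolerance = 1e-6)
})

test_that("floating volumes round-trip within 1e-7 relative", {
  arr <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(volume_grid(arr), path)
  expect_equal(read_volume(path)$data, arr, tolerance = 1e-7)
})

test_that("4D scans load as voxels x timepoints with TR from the header", {
  arr <- array(rnorm(3 * 3 * 3 * 10), dim = c(3, 3, 3, 10))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_scan(scan4d(arr, tr_s = 2), path)
  sc <- read_scan(path)
  expect_equal(dim(sc$data), c(27L, 10L))
  expect_equal(sc$tr_s, 2, tolerance = 1e-6)
  expect_equal(sc$data, matrix(arr, nrow = 27), tolerance = 1e-12)
})

test_that("dimensionality and header defects are rejected", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  img2d <- RNifti::asNifti(matrix(1:4, 2, 2))
  RNifti::writeNifti(img2d, path)
  expect_error(read_volume(path), "3D")
  expect_error(read_volume(withr::local_tempfile(fileext = ".nii")),
               "not found")
  expect_error(volume_grid(array(1, c(2, 2, 2)), voxel_size_mm = c(0, 1, 1)),
               "voxel_size")
  expect_error(scan4d(matrix(1, 8, 1), c(2, 2, 2), 1), "timepoints")
})

test_that("label atlas reader enforces grid/table consistency", {
  lab <- array(0L, dim = c(4, 4, 4))
  lab[1:2, 1, 1] <- 1L
  lab[3:4, 4, 4] <- 7L
  tab <- data.frame(label_id = c(1L, 7L), name = c("a", "b"),
                    hemisphere = c("L", "R"), role = c("target", "target"))
  vp <- withr::local_tempfile(fileext = ".nii.gz")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_label_atlas(label_atlas(lab, tab), vp, tp)
  atl <- read_label_atlas(vp, tp)
  expect_equal(nrow(atl$table), 2L)
  expect_equal(sort(unique(as.vector(atl$labels))), c(0L, 1L, 7L))

  # mutation cases: every grid/table mismatch must be rejected
  expect_error(label_atlas(lab, tab[1, ]), "absent from table")
  expect_error(label_atlas(lab, rbind(tab, tab[1, ])), "duplicate")
  tab_bad_h <- tab; tab_bad_h$hemisphere[1] <- "X"
  expect_error(label_atlas(lab, tab_bad_h), "hemisphere")
  tab_bad_r <- tab; tab_bad_r$role[1] <- "cortex"
  expect_error(label_atlas(lab, tab_bad_r), "role")
  tab0 <- tab; tab0$label_id[1] <- 0L
  expect_error(label_atlas(lab, tab0), "background")
  expect_error(label_atlas(lab - 1L, tab), "non-negative")
})

test_that("fingerprint tables round-trip to full precision with NA dialect", {
  m <- matrix(c(0.123456789012345, -0.5, 0.25, 1), 2, 2,
              dimnames = list(NULL, c("amy", "hip")))
  sem <- matrix(c(0.01, NA, 0.002, 0), 2, 2)
  fp <- fingerprint(m, sem, n = matrix(c(5, 1, 5, 5), 2, 2),
                    seed_positions = c(0.25, 0.75), species = "mouse",
                    modality = "tracer")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprint_table(fp, path)
  lines <- readLines(path)
  expect_length(lines, 5L)  # header + 2 seeds x 2 targets
  expect_true(any(grepl("\tNA\t", lines)))
  back <- read_fingerprint_table(path)
  expect_equal(back$mean_r, fp$mean_r, tolerance = 1e-12)
  expect_equal(back$sem, fp$sem, tolerance = 1e-12)
  expect_equal(back$seed_positions, fp$seed_positions, tolerance = 1e-12)
})

test_that("single-measurement fingerprints carry NA SEM", {
  fp <- fingerprint(matrix(0.5, 1, 2), n = 1L, seed_positions = 0.5)
  expect_true(all(is.na(fp$sem)))
  expect_error(fingerprint(matrix(2, 1, 1), seed_positions = 0.1), "mean_r")
  expect_error(fingerprint(matrix(0.1, 2, 1), seed_positions = c(0.7, 0.2)),
               "increasing")
})
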