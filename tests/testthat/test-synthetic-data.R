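test_that("phantom spec validates its parameters", {
  expect_error(phantom_spec(lesion_radius_range = c(0.3, 0.2)), "increasing")
  expect_error(phantom_spec(lesion_radius_range = c(0, 0.2)), "increasing")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
})

test_that("a noiseless smooth phantom is a thresholdable disc", {
  spec <- phantom_spec(image_size = 64, lesion_boundary_roughness = 0,
                      noise_sigma = 0, bias_field_amplitude = 0,
                      lesion_contrast = 5)
  ph <- generate_phantom(spec, seed = 3)
  # contrast dominates the background, so after [0,1] normalization the
  # lesion is exactly the upper intensity mode
  expect_identical(ph$image > 0.5, ph$mask)
  # with a pinned center/radius the mask is the analytic disc rasterization
  ph2 <- generate_phantom(spec, seed = 3, center = c(32.5, 30.2),
                          mean_radius = 10)
  rows <- matrix(seq_len(64), 64, 64)
  cols <- t(rows)
  disc <- sqrt((rows - 32.5)^2 + (cols - 30.2)^2) <= 10
  expect_identical(ph2$mask, disc)
})

test_that("phantom generation is a pure function of spec and seed", {
  spec <- phantom_spec(image_size = 48)
  a <- generate_phantom(spec, seed = 9)
  b <- generate_phantom(spec, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a$mask, generate_phantom(spec, seed = 10)$mask))
})

test_that("lesion areas follow the generative radii and stay connected", {
  spec <- phantom_spec(image_size = 64)
  areas <- numeric(100)
  for (i in 1:100) {
    ph <- generate_phantom(spec, seed = 4000 + i)
    areas[i] <- mean(ph$mask)
  }
  r <- spec$lesion_radius_range
  # min radius is floored at 3 px on a 64-px side
  r_min_eff <- max(r[1], 3 / spec$image_size)
  expect_gt(min(areas), pi * r_min_eff^2 * 0.8 * 0.9)
  expect_lt(max(areas), pi * r[2]^2 * 1.2)
  for (i in 1:25)
    expect_true(mask_connected(generate_phantom(spec, seed = 7000 + i)$mask))
})

test_that("cohort generation writes a consistent, reproducible manifest", {
  spec <- phantom_spec(image_size = 32, slices_per_patient = 4, seed = 5)
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  mf1 <- generate_cohort(10, spec, d1)
  m <- read_manifest(mf1)
  expect_identical(nrow(m), 40L)
  expect_identical(length(unique(m$patient_id)), 10L)
  expect_true(all(file.exists(m$image_path)))
  expect_true(all(file.exists(m$mask_path)))
  # regeneration under the same seed is byte-identical
  generate_cohort(10, spec, d2)
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  sum1 <- vapply(files, function(f) unname(tools::md5sum(file.path(d1, f))),
                 character(1))
  sum2 <- vapply(files, function(f) unname(tools::md5sum(file.path(d2, f))),
                 character(1))
  expect_identical(sum1, sum2)
})

test_that("slices of one patient share lesion location statistics", {
  spec <- phantom_spec(image_size = 64, slices_per_patient = 4, seed = 8)
  d <- file.path(tempdir(), "coh3")
  unlink(d, recursive = TRUE)
  m <- read_manifest(generate_cohort(6, spec, d))
  centroid <- function(mask) {
    ix <- which(mask, arr.ind = TRUE)
    colMeans(ix)
  }
  cents <- t(vapply(seq_len(nrow(m)), function(i)
    centroid(read_case(m$image_path[i], m$mask_path[i])$mask$grid),
    numeric(2)))
  within <- vapply(split(seq_len(nrow(m)), m$patient_id), function(ix)
    mean(apply(cents[ix, , drop = FALSE], 2, stats::sd)), numeric(1))
  overall <- mean(apply(cents, 2, stats::sd))
  # per-slice jitter (1.5% of the side) is far below the cohort spread
  expect_lt(mean(within), overall)
  expect_lt(mean(within), 0.05 * 64)
})

test_that("patient-level folds partition the cohort evenly", {
  ids <- sprintf("p%03d", 1:300)
  f <- kfold_split(ids, 10, seed = 2)
  expect_identical(as.integer(table(f$assignment)), rep(30L, 10))
  f2 <- kfold_split(sprintf("q%d", 1:7), 3, seed = 1)
  expect_identical(sort(as.integer(table(f2$assignment)), decreasing = TRUE),
                   c(3L, 2L, 2L))
  # partition property: disjoint folds whose union is the cohort
  got <- unlist(lapply(0:9, function(k) fold_patients(f, k)))
  expect_setequal(got, ids)
  expect_identical(anyDuplicated(got), 0L)
  for (k in 0:9)
    expect_length(intersect(fold_patients(f, k), fold_complement(f, k)), 0)
  expect_error(kfold_split(ids[1:5], 10, 1), "exceeds")
  expect_error(kfold_split(ids, 1, 1), "k must be")
})

test_that("image/mask pairs round-trip through PNG and NIfTI", {
  d <- tempdir()
  img <- matrix(round(runif(32 * 24) * 255) / 255, 32, 24)
  msk <- bm(random_mask(32, 24), c(0.5, 0.5))
  write_case(img, msk, file.path(d, "i.png"), file.path(d, "m.png"))
  rc <- read_case(file.path(d, "i.png"), file.path(d, "m.png"))
  expect_identical(rc$image, img)
  expect_identical(rc$mask$grid, msk$grid)
  expect_identical(rc$mask$spacing, c(1, 1))   # PNG carries no spacing
  write_case(img, msk, file.path(d, "i.nii.gz"), file.path(d, "m.nii.gz"))
  rn <- read_case(file.path(d, "i.nii.gz"), file.path(d, "m.nii.gz"))
  expect_equal(rn$image, img, tolerance = 1e-12)
  expect_identical(rn$mask$grid, msk$grid)
  expect_identical(rn$mask$spacing, c(0.5, 0.5))
})

test_that("case reading rejects missing, mismatched and non-binary files", {
  d <- tempdir()
  expect_error(read_case(file.path(d, "absent.png"), file.path(d, "m.png")),
               "not found")
  img <- matrix(0.5, 8, 8)
  write_case(img, bm(random_mask(8, 8)), file.path(d, "a.png"),
             file.path(d, "am.png"))
  write_case(matrix(0.5, 6, 6), bm(random_mask(6, 6)), file.path(d, "b.png"),
             file.path(d, "bm.png"))
  expect_error(read_case(file.path(d, "a.png"), file.path(d, "bm.png")),
               "shapes differ")
  bad <- RNifti::asNifti(matrix(c(0, 1, 2, 0), 2, 2))
  RNifti::writeNifti(bad, file.path(d, "bad.nii"))
  okimg <- RNifti::asNifti(matrix(0.5, 2, 2))
  RNifti::writeNifti(okimg, file.path(d, "okimg.nii"))
  expect_error(read_case(file.path(d, "okimg.nii"), file.path(d, "bad.nii")),
               "not binary")
})
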