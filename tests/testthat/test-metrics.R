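test_that("dice matches hand-counted fixtures and is symmetric", {
  A <- matrix(FALSE, 8, 8); A[3:4, 3:4] <- TRUE           # |A| = 4
  B <- matrix(FALSE, 8, 8); B[3:4, 3:6] <- TRUE           # |B| = 8, overlap 4
  expect_equal(dice(bm(A), bm(B)), 2 * 4 / 12)
  expect_equal(dice(bm(B), bm(A)), dice(bm(A), bm(B)))
  expect_identical(dice(bm(A), bm(A)), 1)
  C <- matrix(FALSE, 8, 8); C[6:7, 6:7] <- TRUE
  expect_identical(dice(bm(A), bm(C)), 0)
})

test_that("dice raises on shape mismatch and the double-empty case", {
  expect_error(dice(bm(matrix(TRUE, 2, 2)), bm(matrix(TRUE, 3, 3))),
               "shapes differ")
  e <- matrix(FALSE, 4, 4)
  expect_error(dice(bm(e), bm(e)), "undefined")
  # one empty side is well defined (no overlap)
  expect_identical(dice(bm(e), bm(matrix(TRUE, 4, 4))), 0)
})

test_that("dice is spacing-invariant; masks validate values", {
  A <- random_mask(6, 6); B <- random_mask(6, 6)
  expect_identical(dice(bm(A, 1), bm(B, 1)), dice(bm(A, 3), bm(B, 3)))
  expect_error(binary_mask(matrix(c(0, 1, 2, 0), 2)), "non-binary")
})

test_that("surface extraction returns boundary pixels only", {
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_identical(unname(extract_surface(bm(single))$points),
                   matrix(c(3L, 3L), 1))
  sq <- matrix(FALSE, 8, 8); sq[3:6, 3:6] <- TRUE
  pts <- extract_surface(bm(sq))$points
  expect_identical(nrow(pts), 12L)                 # 4x4 square: 12 boundary px
  expect_false(any(pts[, 1] %in% 4:5 & pts[, 2] %in% 4:5))  # interior excluded
  # the image border counts as background: a full mask is all surface at the
  # border, and only there
  full <- matrix(TRUE, 4, 5)
  pf <- extract_surface(bm(full))$points
  expect_identical(nrow(pf), 2L * 4L + 2L * 5L - 4L)
  expect_true(all(pf[, 1] %in% c(1, 4) | pf[, 2] %in% c(1, 5)))
  expect_error(extract_surface(bm(matrix(FALSE, 3, 3))), "empty")
})

test_that("assd reproduces hand-computed distances", {
  a <- matrix(FALSE, 8, 8); a[4, 2] <- TRUE
  b <- matrix(FALSE, 8, 8); b[4, 5] <- TRUE
  expect_equal(assd(bm(a), bm(b)), 3)              # two points, both 3 px
  expect_identical(assd(bm(a), bm(a)), 0)
  sq <- matrix(FALSE, 10, 10); sq[3:5, 3:5] <- TRUE
  sh <- matrix(FALSE, 10, 10); sh[3:5, 4:6] <- TRUE
  expect_equal(assd(bm(sq), bm(sh)), assd_bruteforce(bm(sq), bm(sh)),
               tolerance = 1e-12)
})

test_that("assd agrees with the all-pairs oracle on random mask pairs", {
  set.seed(31)
  worst <- 0
  for (i in 1:60) {
    H <- sample(4:14, 1); W <- sample(4:14, 1)
    A <- bm(random_mask(H, W), runif(1, 0.4, 2))
    B <- bm(random_mask(H, W), A$spacing)
    worst <- max(worst, abs(assd(A, B) - assd_bruteforce(A, B)))
  }
  expect_lt(worst, 1e-9)
})

test_that("assd is symmetric, scales with spacing, and validates inputs", {
  set.seed(7)
  A <- bm(random_mask(9, 9)); B <- bm(random_mask(9, 9))
  expect_equal(assd(A, B), assd(B, A))
  for (s in c(0.5, 2, 3.7))
    expect_equal(assd(bm(A$grid, s), bm(B$grid, s)), s * assd(A, B),
                 tolerance = 1e-12)
  expect_error(assd(bm(A$grid, 1), bm(B$grid, 2)), "spacings differ")
  expect_error(assd(A, bm(matrix(FALSE, 9, 9))), "empty")
  # anisotropic spacing: a 1-row offset costs row_mm
  a <- matrix(FALSE, 6, 6); a[2, 3] <- TRUE
  b <- matrix(FALSE, 6, 6); b[4, 3] <- TRUE
  expect_equal(assd(bm(a, c(0.5, 2)), bm(b, c(0.5, 2))), 1)
})

test_that("evaluate_case bundles metrics and records undefined ones", {
  m <- random_mask(8, 8)
  r <- evaluate_case(bm(m), bm(m))
  expect_identical(r$dsc, 1)
  expect_identical(r$assd_mm, 0)
  expect_length(r$undefined, 0)
  a <- matrix(FALSE, 8, 8); a[2, 2] <- TRUE
  c2 <- matrix(FALSE, 8, 8); c2[6, 6] <- TRUE
  r2 <- evaluate_case(bm(a), bm(c2))
  expect_identical(r2$dsc, 0)
  expect_gt(r2$assd_mm, 0)
  # empty prediction: DSC defined (0), ASSD undefined
  r3 <- evaluate_case(bm(matrix(FALSE, 8, 8)), bm(m))
  expect_identical(r3$dsc, 0)
  expect_true(is.na(r3$assd_mm))
  expect_identical(r3$undefined, "assd")
})
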