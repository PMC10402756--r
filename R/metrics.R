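#' Binary segmentation mask with physical pixel spacing
#'
#' @param grid Logical (or 0/1) `H x W` matrix; `TRUE`/1 is foreground.
#'   Coordinates are (row, col), origin top-left.
#' @param spacing Positive numeric `c(row_mm, col_mm)` pixel spacing in mm;
#'   a scalar is used for both axes (default 1 mm isotropic).
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(grid, spacing = c(1, 1)) {
  stop_if_not(is.matrix(grid), "mask grid must be a matrix")
  if (is.numeric(grid)) {
    bad <- !(grid %in% c(0, 1))
    if (any(bad))
      stop(sprintf("mask contains %d non-binary values (e.g. %g)", sum(bad),
                   grid[bad][1]), call. = FALSE)
    grid <- grid == 1
  }
  stop_if_not(is.logical(grid), "mask grid must be logical or 0/1")
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  stop_if_not(length(spacing) == 2 && all(is.finite(spacing)) &&
                all(spacing > 0), "spacing must be two positive numbers (mm)")
  structure(list(grid = grid, spacing = as.numeric(spacing)),
            class = "binary_mask")
}

as_binary_mask <- function(m, spacing = c(1, 1)) {
  if (inherits(m, "binary_mask")) m else binary_mask(m, spacing)
}

check_same_shape <- function(A, B) {
  if (!all(dim(A$grid) == dim(B$grid)))
    stop(sprintf("mask shapes differ: %dx%d vs %dx%d", nrow(A$grid),
                 ncol(A$grid), nrow(B$grid), ncol(B$grid)), call. = FALSE)
}

#' Dice similarity coefficient
#'
#' Overlap between two binary masks, `2|A n B| / (|A| + |B|)`, in `[0, 1]`:
#' 0 means no spatial overlap, 1 complete overlap.  Spacing plays no role.
#'
#' @param A,B [binary_mask()] objects (or logical matrices) of equal shape,
#'   not both empty.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(A, B) {
  A <- as_binary_mask(A)
  B <- as_binary_mask(B)
  check_same_shape(A, B)
  nA <- sum(A$grid)
  nB <- sum(B$grid)
  if (nA + nB == 0)
    stop("DSC is undefined for two empty masks", call. = FALSE)
  2 * sum(A$grid & B$grid) / (nA + nB)
}

#' Extract the surface of a binary mask
#'
#' Surface pixels are the foreground pixels with at least one background
#' 4-neighbor; the image border counts as background, so a mask touching the
#' border contributes its border pixels.
#'
#' @param M A [binary_mask()] (or logical matrix); must be nonempty.
#' @return List with `points` (n x 2 integer matrix of (row, col), 1-based)
#'   and `spacing` (mm).
#' @export
extract_surface <- function(M) {
  M <- as_binary_mask(M)
  g <- M$grid
  if (!any(g)) stop("cannot extract the surface of an empty mask",
                    call. = FALSE)
  H <- nrow(g); W <- ncol(g)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- g
  core <- pad[2:(H + 1), 2:(W + 1)] &
    pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  surf <- g & !core
  idx <- which(surf, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  list(points = idx, spacing = M$spacing, grid_dim = c(H, W))
}

#' Average symmetric surface distance (ASSD)
#'
#' Mean over both surfaces of the shortest Euclidean distance (between pixel
#' centers, in mm, honoring anisotropic spacing) from each surface pixel of
#' one mask to the surface of the other:
#' `(sum_a d(a, S_B) + sum_b d(b, S_A)) / (|S_A| + |S_B|)`.
#' Computed with an exact Euclidean distance transform; [assd_bruteforce()]
#' is the all-pairs reference.
#'
#' @param A,B [binary_mask()] objects of equal shape and spacing, both
#'   nonempty.
#' @return ASSD in mm (0 iff the two surfaces coincide).
#' @export
assd <- function(A, B) {
  A <- as_binary_mask(A)
  B <- as_binary_mask(B)
  check_same_shape(A, B)
  if (!isTRUE(all.equal(A$spacing, B$spacing)))
    stop("mask spacings differ", call. = FALSE)
  sa <- extract_surface(A)
  sb <- extract_surface(B)
  surf_a <- matrix(FALSE, nrow(A$grid), ncol(A$grid))
  surf_a[sa$points] <- TRUE
  surf_b <- matrix(FALSE, nrow(B$grid), ncol(B$grid))
  surf_b[sb$points] <- TRUE
  Db <- cpp_edt_sq(surf_b, A$spacing[1], A$spacing[2])  # distance to S_B
  Da <- cpp_edt_sq(surf_a, A$spacing[1], A$spacing[2])  # distance to S_A
  d_ab <- sqrt(Db[sa$points])
  d_ba <- sqrt(Da[sb$points])
  (sum(d_ab) + sum(d_ba)) / (length(d_ab) + length(d_ba))
}

#' All-pairs reference implementation of ASSD
#'
#' Exhaustive pairwise distances between the two surface point sets;
#' quadratic cost, intended as a test oracle for [assd()].
#'
#' @inheritParams assd
#' @return ASSD in mm.
#' @export
assd_bruteforce <- function(A, B) {
  A <- as_binary_mask(A)
  B <- as_binary_mask(B)
  check_same_shape(A, B)
  if (!isTRUE(all.equal(A$spacing, B$spacing)))
    stop("mask spacings differ", call. = FALSE)
  pa <- extract_surface(A)$points
  pb <- extract_surface(B)$points
  sr <- A$spacing[1]; sc <- A$spacing[2]
  D2 <- outer(pa[, 1] * sr, pb[, 1] * sr, "-")^2 +
    outer(pa[, 2] * sc, pb[, 2] * sc, "-")^2
  (sum(sqrt(apply(D2, 1, min))) + sum(sqrt(apply(D2, 2, min)))) /
    (nrow(pa) + nrow(pb))
}

#' Evaluate one predicted mask against its reference
#'
#' Bundles [dice()] and [assd()].  Metrics that are undefined for the case
#' (DSC when both masks are empty; ASSD when either mask is empty) are
#' recorded as `NA` and named in `undefined` rather than raised, so fold
#' aggregation can exclude and count them.
#'
#' @param pred,truth [binary_mask()] objects of equal shape and spacing.
#' @return List with `dsc`, `assd_mm` and `undefined` (character vector).
#' @export
evaluate_case <- function(pred, truth) {
  pred <- as_binary_mask(pred)
  truth <- as_binary_mask(truth)
  undefined <- character()
  dsc <- tryCatch(dice(pred, truth), error = function(e) {
    undefined <<- c(undefined, "dsc")
    NA_real_
  })
  assd_mm <- tryCatch(assd(pred, truth), error = function(e) {
    undefined <<- c(undefined, "assd")
    NA_real_
  })
  list(dsc = dsc, assd_mm = assd_mm, undefined = undefined)
}
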