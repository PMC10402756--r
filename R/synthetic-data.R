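# MRI-like phantom cohorts: smooth anatomical background, one star-convex
# bright (or dark) lesion per slice, multiplicative low-frequency bias field,
# additive Gaussian noise; slices grouped into synthetic patients that share
# lesion location statistics.  Coordinates are (row, col), 0-origin top-left;
# mask foreground is 1.

#' Phantom generation parameters
#'
#' @param image_size Side length in pixels (default 128; use 512 for
#'   full-scale runs).  Must be divisible by `2^n_stages` of the network the
#'   cohort will feed.
#' @param slices_per_patient Slices per synthetic patient (default 4).
#' @param lesion_radius_range Mean lesion radius as a fraction of the image
#'   side, drawn uniformly from this range (default 0.05-0.20).
#' @param lesion_contrast Additive intensity offset of the lesion interior
#'   before noise/bias, in the arbitrary units of the background (default
#'   0.4; negative gives a dark lesion).
#' @param lesion_boundary_roughness Relative amplitude of the smooth angular
#'   perturbation of the lesion radius (default 0.15; 0 gives a disc).
#' @param background_smoothness Low-pass scale of the background field in
#'   pixels (default 32).
#' @param noise_sigma Additive Gaussian noise standard deviation in intensity
#'   units (default 0.05).
#' @param bias_field_amplitude Relative amplitude of the multiplicative
#'   low-frequency gain field (default 0.1).
#' @param seed Integer seed making cohort generation a pure function of the
#'   spec (default 1).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 128L, slices_per_patient = 4L,
                         lesion_radius_range = c(0.05, 0.20),
                         lesion_contrast = 0.4,
                         lesion_boundary_roughness = 0.15,
                         background_smoothness = 32,
                         noise_sigma = 0.05, bias_field_amplitude = 0.1,
                         seed = 1L) {
  stop_if_not(image_size >= 8, "image_size must be at least 8 pixels")
  stop_if_not(slices_per_patient >= 1, "slices_per_patient must be >= 1")
  stop_if_not(length(lesion_radius_range) == 2 &&
                lesion_radius_range[1] > 0 && lesion_radius_range[2] < 0.5 &&
                lesion_radius_range[1] <= lesion_radius_range[2],
              "lesion_radius_range must be increasing and within (0, 0.5)")
  stop_if_not(noise_sigma >= 0, "noise_sigma must be >= 0")
  stop_if_not(bias_field_amplitude >= 0, "bias_field_amplitude must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 slices_per_patient = as.integer(slices_per_patient),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 lesion_contrast = lesion_contrast,
                 lesion_boundary_roughness = lesion_boundary_roughness,
                 background_smoothness = background_smoothness,
                 noise_sigma = noise_sigma,
                 bias_field_amplitude = bias_field_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth random field: standard-normal coarse grid bilinearly upsampled
smooth_field <- function(S, scale) {
  n <- max(2L, as.integer(round(S / max(scale, 1))))
  coarse <- array(rnorm((n + 1)^2), c(n + 1, n + 1, 1, 1))
  f <- cpp_resize_bilinear_fwd(coarse, S, S)[, , 1, 1]
  f / max(stats::sd(f), 1e-8)
}

#' Generate one phantom image/mask pair
#'
#' Draws a smooth background, carves one star-convex lesion (mean radius from
#' `lesion_radius_range`, radius perturbed by a smooth angular harmonic
#' series scaled by `lesion_boundary_roughness`), offsets the lesion interior
#' by `lesion_contrast`, applies the multiplicative bias field and additive
#' noise, and min-max normalizes the image to `[0, 1]`.  The mask is exactly
#' the lesion interior.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (cohort generation derives per-slice seeds deterministically).
#' @param center,mean_radius Optional overrides (pixels) used by
#'   [generate_cohort()] to keep a patient's slices spatially coherent.
#' @return List with `image` (`S x S` matrix in `[0, 1]`) and `mask`
#'   (`S x S` logical matrix, one 4-connected lesion).
#' @export
generate_phantom <- function(spec, seed = NULL, center = NULL,
                             mean_radius = NULL) {
  stop_if_not(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  gen <- function() {
    S <- spec$image_size
    bg <- 0.35 + 0.08 * smooth_field(S, spec$background_smoothness)
    if (is.null(center)) center <- runif(2, 0.35, 0.65) * S
    if (is.null(mean_radius))
      mean_radius <- runif(1, spec$lesion_radius_range[1],
                           spec$lesion_radius_range[2]) * S
    r0 <- max(mean_radius, 3)
    rough <- spec$lesion_boundary_roughness
    harmonics <- 2:6
    a <- rnorm(length(harmonics), 0, rough / sqrt(length(harmonics)))
    b <- rnorm(length(harmonics), 0, rough / sqrt(length(harmonics)))
    rows <- matrix(seq_len(S), S, S)
    cols <- matrix(seq_len(S), S, S, byrow = TRUE)
    dr <- rows - center[1]
    dc <- cols - center[2]
    theta <- atan2(dc, dr)
    pert <- matrix(0, S, S)
    for (i in seq_along(harmonics))
      pert <- pert + a[i] * cos(harmonics[i] * theta) +
        b[i] * sin(harmonics[i] * theta)
    radius <- r0 * pmax(1 + pert, 0.3)
    mask <- sqrt(dr^2 + dc^2) <= radius
    img <- bg + spec$lesion_contrast * mask
    if (spec$bias_field_amplitude > 0)
      img <- img * (1 + spec$bias_field_amplitude * smooth_field(S, S / 2))
    if (spec$noise_sigma > 0)
      img <- img + rnorm(S * S) * spec$noise_sigma
    rg <- range(img)
    img <- if (diff(rg) > 0) (img - rg[1]) / diff(rg) else img * 0
    list(image = img, mask = mask)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a phantom cohort on disk
#'
#' Writes `n_patients * slices_per_patient` image/mask pairs plus a manifest
#' CSV (columns `patient_id`, `slice_id`, `image_path`, `mask_path`; paths
#' relative to the manifest) and the spec as a YAML sidecar.  Per-patient
#' sub-seeds are derived deterministically from `spec$seed`, and a patient's
#' slices share lesion location statistics (small per-slice jitter around a
#' patient-level center and radius).
#'
#' @param n_patients Number of synthetic patients (>= 1).
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if needed).
#' @param format `"png"` (8-bit grayscale) or `"nifti"` (float, carries
#'   spacing).
#' @param spacing Pixel spacing in mm written to NIfTI headers (default 1).
#' @return Path of the manifest CSV, invisibly readable with
#'   [read_manifest()].
#' @export
generate_cohort <- function(n_patients, spec, out_dir,
                            format = c("png", "nifti"), spacing = c(1, 1)) {
  stop_if_not(n_patients >= 1, "n_patients must be >= 1")
  format <- match.arg(format)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  ext <- if (format == "png") ".png" else ".nii.gz"
  rows <- vector("list", n_patients * spec$slices_per_patient)
  r <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("p%03d", p)
    pseed <- child_seed(spec$seed, p)
    base <- with_seed(pseed, list(
      center = runif(2, 0.38, 0.62) * spec$image_size,
      radius = runif(1, spec$lesion_radius_range[1],
                     spec$lesion_radius_range[2]) * spec$image_size))
    for (s in seq_len(spec$slices_per_patient)) {
      sseed <- child_seed(pseed, s)
      jitter <- with_seed(sseed, list(center = rnorm(2, 0, 0.015 *
                                                       spec$image_size),
                                      radius = rnorm(1, 0, 0.03 *
                                                       spec$image_size)))
      case <- generate_phantom(spec, seed = child_seed(sseed, 999L),
                               center = base$center + jitter$center,
                               mean_radius = max(base$radius + jitter$radius,
                                                 3))
      img_rel <- sprintf("%s_s%02d_image%s", pid, s, ext)
      msk_rel <- sprintf("%s_s%02d_mask%s", pid, s, ext)
      write_case(case$image, binary_mask(case$mask, spacing),
                 file.path(out_dir, img_rel), file.path(out_dir, msk_rel))
      r <- r + 1L
      rows[[r]] <- data.frame(patient_id = pid, slice_id = s,
                              image_path = img_rel, mask_path = msk_rel,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  yaml::write_yaml(unclass(spec), file.path(out_dir, "phantom_spec.yaml"))
  invisible(manifest_path)
}

#' Read a cohort manifest
#' @param manifest_path Path to a `manifest.csv` written by
#'   [generate_cohort()].
#' @return Data frame with `patient_id`, `slice_id`, `image_path`,
#'   `mask_path` (paths resolved against the manifest directory).
#' @export
read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest '%s' not found", manifest_path), call. = FALSE)
  m <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "slice_id", "image_path", "mask_path")
  stop_if_not(all(need %in% names(m)),
              "manifest must have columns %s", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  m$image_path <- file.path(base, m$image_path)
  m$mask_path <- file.path(base, m$mask_path)
  m
}

load_cases <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    cs <- read_case(manifest$image_path[i], manifest$mask_path[i])
    cs$patient_id <- manifest$patient_id[i]
    cs$slice_id <- manifest$slice_id[i]
    cs
  })
}

#' Patient-level k-fold split
#'
#' Shuffles the patient ids under `seed` and deals them round-robin into `k`
#' folds, so fold sizes differ by at most one and no patient's slices can
#' appear on both sides of a train/validation split.
#'
#' @param patient_ids Character vector of unique patient ids.
#' @param k Number of folds (>= 2, <= number of patients).
#' @param seed Integer shuffle seed.
#' @return A `fold_assignment`: list with `k` and `assignment`, a named
#'   integer vector mapping patient id to fold index in `[0, k)`.
#' @export
kfold_split <- function(patient_ids, k, seed = 1L) {
  stop_if_not(!anyDuplicated(patient_ids), "patient ids must be unique")
  stop_if_not(k >= 2, "k must be >= 2")
  if (k > length(patient_ids))
    stop(sprintf("k = %d exceeds the number of patients (%d)", k,
                 length(patient_ids)), call. = FALSE)
  shuffled <- with_seed(seed, sample(patient_ids))
  assignment <- stats::setNames((seq_along(shuffled) - 1L) %% as.integer(k),
                                shuffled)
  structure(list(k = as.integer(k), assignment = assignment[patient_ids]),
            class = "fold_assignment")
}

#' Fold membership helpers
#' @param folds A [kfold_split()] result.
#' @param fold Fold index in `[0, k)`.
#' @return Character vector of patient ids in (`fold_patients`) or out of
#'   (`fold_complement`) the given fold.
#' @export
fold_patients <- function(folds, fold) {
  names(folds$assignment)[folds$assignment == fold]
}

#' @rdname fold_patients
#' @export
fold_complement <- function(folds, fold) {
  names(folds$assignment)[folds$assignment != fold]
}

# ---- case I/O --------------------------------------------------------------

read_gray_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  v
}

#' Write an image/mask pair
#'
#' PNG files are 8-bit grayscale (images quantized to 256 levels, masks
#' stored as 0/255, both round-tripping exactly); NIfTI files keep float
#' intensities and record the pixel spacing in the header.
#'
#' @param image `H x W` numeric matrix in `[0, 1]`.
#' @param mask A [binary_mask()] of the same shape.
#' @param image_path,mask_path Destination paths; format chosen by extension
#'   (`.png`, `.nii`, `.nii.gz`).
#' @export
write_case <- function(image, mask, image_path, mask_path) {
  mask <- as_binary_mask(mask)
  stop_if_not(all(dim(image) == dim(mask$grid)),
              "image and mask dimensions differ")
  write_one <- function(x, path, is_mask) {
    if (grepl("\\.png$", path)) {
      png::writePNG(round(x * 255) / 255, path)
    } else if (grepl("\\.nii(\\.gz)?$", path)) {
      img <- RNifti::asNifti(x)
      RNifti::pixdim(img) <- mask$spacing
      RNifti::writeNifti(img, path)
    } else stop(sprintf("unsupported image format: '%s'", path),
                call. = FALSE)
  }
  write_one(image, image_path, FALSE)
  write_one(mask$grid * 1.0, mask_path, TRUE)
  invisible(c(image_path, mask_path))
}

#' Read an image/mask pair
#'
#' Supports 8/16-bit grayscale PNG and 2D NIfTI (`.nii`, `.nii.gz`; the first
#' slice of a volume is taken).  NIfTI spacing populates the mask's
#' `spacing`; PNG masks default to 1 mm.  Mask files must be strictly binary.
#'
#' @param image_path,mask_path Paths written by [write_case()] or compatible.
#' @return List with `image` (numeric matrix) and `mask` (a [binary_mask()]).
#' @export
read_case <- function(image_path, mask_path) {
  for (p in c(image_path, mask_path))
    if (!file.exists(p)) stop(sprintf("file '%s' not found", p),
                              call. = FALSE)
  read_one <- function(path) {
    if (grepl("\\.png$", path)) {
      list(values = read_gray_png(path), spacing = c(1, 1))
    } else if (grepl("\\.nii(\\.gz)?$", path)) {
      v <- RNifti::readNifti(path)
      sp <- as.numeric(RNifti::pixdim(v)[1:2])
      v <- as.array(v)
      if (length(dim(v)) == 3) v <- v[, , 1]
      v <- matrix(as.numeric(v), nrow(v), ncol(v))  # drop NIfTI attributes
      list(values = v, spacing = sp)
    } else stop(sprintf("unsupported image format: '%s'", path),
                call. = FALSE)
  }
  img <- read_one(image_path)
  msk <- read_one(mask_path)
  if (!all(dim(img$values) == dim(msk$values)))
    stop(sprintf("image (%dx%d) and mask (%dx%d) shapes differ",
                 nrow(img$values), ncol(img$values), nrow(msk$values),
                 ncol(msk$values)), call. = FALSE)
  mv <- msk$values
  is_one <- abs(mv - max(mv)) < 1e-6 & max(mv) > 0
  is_zero <- abs(mv) < 1e-6
  if (!all(is_one | is_zero) || (max(mv) > 0 && abs(max(mv) - 1) > 1e-6))
    stop(sprintf("mask '%s' is not binary (values outside {0, 1})",
                 mask_path), call. = FALSE)
  list(image = img$values,
       mask = binary_mask(mv > 0.5, msk$spacing))
}

#' Is a mask a single 4-connected component?
#'
#' Flood fill from one foreground pixel; used to verify that phantom lesions
#' are single connected regions.
#'
#' @param mask Logical matrix.
#' @return `TRUE` if the foreground is nonempty and 4-connected.
#' @export
mask_connected <- function(mask) {
  n_fg <- sum(mask)
  if (n_fg == 0) return(FALSE)
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  start <- which(mask)[1]
  stack <- start
  seen[start] <- TRUE
  count <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    count <- count + 1L
    i <- (v - 1L) %% H + 1L
    j <- (v - 1L) %/% H + 1L
    for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
      if (nb[1] >= 1 && nb[1] <= H && nb[2] >= 1 && nb[2] <= W) {
        u <- (nb[2] - 1L) * H + nb[1]
        if (mask[u] && !seen[u]) {
          seen[u] <- TRUE
          stack <- c(stack, u)
        }
      }
    }
  }
  count == n_fg
}
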