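#' Effective kernel size of a dilated convolution
#'
#' A dilated (atrous) convolution with original kernel side `K` and dilation
#' rate `R` spaces the kernel taps `R - 1` zeros apart, so the footprint on
#' the input — the effective kernel side — is `D = K + (K - 1)(R - 1)`.
#' A 3x3 kernel at rate 2 covers 5x5; at rate 3 it covers 7x7; `R = 1`
#' recovers the standard convolution.
#'
#' @param K Odd positive integer, original kernel side length in pixels.
#' @param R Positive integer dilation rate (dimensionless).
#' @return Integer effective kernel side length `D` (odd whenever `K` is odd).
#' @examples
#' effective_kernel_size(3, 2) # 5
#' effective_kernel_size(3, 3) # 7
#' @export
effective_kernel_size <- function(K, R) {
  stop_if_not(length(K) == 1 && length(R) == 1 && is.finite(K) && is.finite(R),
              "K and R must be single finite numbers")
  stop_if_not(K == as.integer(K) && R == as.integer(R),
              "K and R must be integers")
  stop_if_not(K >= 1, "kernel size K must be positive (got %s)", K)
  stop_if_not(K %% 2 == 1, "kernel size K must be odd (got %s)", K)
  stop_if_not(R >= 1, "dilation rate R must be positive (got %s)", R)
  as.integer(K + (K - 1) * (R - 1))
}

#' Rectified linear activation
#'
#' Elementwise `max(0, x)`: negative activations are clipped to zero,
#' non-negative ones pass through unchanged.
#'
#' @param x Numeric array or vector.
#' @return Object of the same shape with negative entries replaced by 0.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# coerce a matrix / (H,W,C) array to the canonical (H, W, C, N) layout
as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature maps must be matrices or arrays", call. = FALSE)
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3) dim(x) <- c(d, 1L)
  else if (length(d) != 4) stop("feature maps have at most 4 dims", call. = FALSE)
  stop_if_not(all(dim(x) >= 1), "all feature-map dims must be >= 1")
  stop_if_not(all(is.finite(x)), "feature-map values must be finite")
  x
}

#' Dilated 2D convolution with "same" zero padding
#'
#' Applies a dilated convolution whose taps are spaced `dilation - 1` zeros
#' apart, zero-padding the input by `(D - 1) / 2` per side (with `D` the
#' [effective_kernel_size()]) so the output spatial size equals the input
#' spatial size.
#'
#' @param x Feature map: `(H, W)` matrix, `(H, W, C)` or `(H, W, C, N)` array.
#' @param weights Kernel array `(K, K, in_channels, out_channels)`, `K` odd.
#' @param bias Numeric vector of length `out_channels` (default zeros).
#' @param dilation Positive integer dilation rate.
#' @return Feature map array `(H, W, out_channels, N)`.
#' @examples
#' w <- array(0, c(3, 3, 1, 1)); w[2, 2, 1, 1] <- 1   # identity kernel
#' x <- matrix(rnorm(64), 8, 8)
#' all.equal(dilated_conv(x, w, dilation = 4)[, , 1, 1], x)
#' @export
dilated_conv <- function(x, weights, bias = NULL, dilation = 1L) {
  x <- as_feature_map(x)
  d <- dim(weights)
  stop_if_not(length(d) == 4 && d[1] == d[2],
              "weights must be a (K, K, in, out) array")
  effective_kernel_size(d[1], dilation)  # validates K odd, dilation >= 1
  if (is.null(bias)) bias <- numeric(d[4])
  cpp_conv2d_fwd(x, weights, bias, as.integer(dilation))
}
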