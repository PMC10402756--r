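# Spatial layers.  All operate on (H, W, C, N) arrays.

# sum of `a` per channel, over H, W and N
channel_sum <- function(a, C) {
  d <- dim(a)
  HW <- d[1] * d[2]
  rowSums(matrix(colSums(matrix(a, HW)), C, d[4]))
}

# broadcast a length-C vector over (H, W, C, N); relies on vector recycling
# across the trailing batch dimension
bcast_c <- function(v, HW) rep(v, each = HW)

#' Convolution layer (dilated, shape-preserving)
#'
#' A learnable dilated 2D convolution with "same" zero padding and bias,
#' He-uniform initialized from the current RNG stream.
#'
#' @param in_ch,out_ch Input / output channel counts.
#' @param kernel Odd kernel side (default 3).
#' @param dilation Dilation rate (default 1 = standard convolution).
#' @return A module usable with [nn_forward()] / [nn_backward()].
#' @export
layer_conv2d <- function(in_ch, out_ch, kernel = 3L, dilation = 1L) {
  effective_kernel_size(kernel, dilation)
  w <- init_he(c(kernel, kernel, in_ch, out_ch), fan_in = kernel^2 * in_ch)
  new_module("layer_conv2d", kernel = as.integer(kernel),
             dilation = as.integer(dilation),
             in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
             params = list(w = new_param(w), b = new_param(numeric(out_ch))))
}

#' @export
nn_forward.layer_conv2d <- function(mod, x, train = FALSE) {
  if (dim(x)[3] != mod$in_ch)
    stop(sprintf("channel mismatch: input has %d channels, layer expects %d",
                 dim(x)[3], mod$in_ch), call. = FALSE)
  if (train) mod$cache$x <- x
  cpp_conv2d_fwd(x, mod$params$w$v, mod$params$b$v, mod$dilation)
}

#' @export
nn_backward.layer_conv2d <- function(mod, dy) {
  g <- cpp_conv2d_bwd(mod$cache$x, mod$params$w$v, dy, mod$dilation)
  mod$params$w$g <- mod$params$w$g + g$dw
  mod$params$b$g <- mod$params$b$g + g$db
  g$dx
}

#' ReLU layer
#' @return A module computing elementwise `max(0, x)`.
#' @export
layer_relu <- function() new_module("layer_relu")

#' @export
nn_forward.layer_relu <- function(mod, x, train = FALSE) {
  if (train) mod$cache$mask <- x > 0
  relu(x)
}

#' @export
nn_backward.layer_relu <- function(mod, dy) dy * mod$cache$mask

#' Batch normalization layer
#'
#' Per-channel normalization over the batch and spatial dims with learnable
#' scale/shift; evaluation mode uses exponentially averaged running moments.
#'
#' @param C Channel count.
#' @param momentum Running-moment update rate (default 0.1).
#' @param eps Variance floor (default 1e-5).
#' @export
layer_batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  mod <- new_module("layer_batchnorm", C = as.integer(C), momentum = momentum,
                    eps = eps,
                    params = list(gamma = new_param(rep(1, C)),
                                  beta = new_param(numeric(C))))
  mod$state$running_mean <- numeric(C)
  mod$state$running_var <- rep(1, C)
  mod$state$n_updates <- 0L
  mod
}

#' @export
nn_forward.layer_batchnorm <- function(mod, x, train = FALSE) {
  d <- dim(x)
  HW <- d[1] * d[2]
  C <- mod$C
  # before any training update the running moments are uninformative
  # (mean 0, var 1); evaluation then standardizes with batch statistics
  if (train || mod$state$n_updates == 0L) {
    m <- HW * d[4]
    mu <- channel_sum(x, C) / m
    v <- channel_sum(x^2, C) / m - mu^2
    ivar <- 1 / sqrt(v + mod$eps)
    xhat <- (x - bcast_c(mu, HW)) * bcast_c(ivar, HW)
    if (train) {
      mod$cache$xhat <- xhat
      mod$cache$ivar <- ivar
      mod$cache$m <- m
      mod$state$running_mean <- (1 - mod$momentum) * mod$state$running_mean +
        mod$momentum * mu
      mod$state$running_var <- (1 - mod$momentum) * mod$state$running_var +
        mod$momentum * v
      mod$state$n_updates <- mod$state$n_updates + 1L
    }
  } else {
    ivar <- 1 / sqrt(mod$state$running_var + mod$eps)
    xhat <- (x - bcast_c(mod$state$running_mean, HW)) * bcast_c(ivar, HW)
  }
  xhat * bcast_c(mod$params$gamma$v, HW) + bcast_c(mod$params$beta$v, HW)
}

#' @export
nn_backward.layer_batchnorm <- function(mod, dy) {
  d <- dim(dy)
  HW <- d[1] * d[2]
  C <- mod$C
  xhat <- mod$cache$xhat
  m <- mod$cache$m
  dxhat <- dy * bcast_c(mod$params$gamma$v, HW)
  s1 <- channel_sum(dxhat, C)
  s2 <- channel_sum(dxhat * xhat, C)
  dx <- bcast_c(mod$cache$ivar, HW) *
    (dxhat - bcast_c(s1 / m, HW) - xhat * bcast_c(s2 / m, HW))
  mod$params$gamma$g <- mod$params$gamma$g + channel_sum(dy * xhat, C)
  mod$params$beta$g <- mod$params$beta$g + channel_sum(dy, C)
  dx
}

#' Group normalization layer
#'
#' Normalizes over the spatial dims and the channels of each group,
#' independently per sample, so statistics do not depend on batch size.
#'
#' @param C Channel count.
#' @param groups Number of channel groups; defaults to the largest divisor of
#'   `C` that is at most 8.
#' @param eps Variance floor.
#' @export
layer_groupnorm <- function(C, groups = NULL, eps = 1e-5) {
  if (is.null(groups)) groups <- max(which(C %% seq_len(min(8, C)) == 0))
  stop_if_not(C %% groups == 0, "groups must divide the channel count")
  new_module("layer_groupnorm", C = as.integer(C), groups = as.integer(groups),
             eps = eps,
             params = list(gamma = new_param(rep(1, C)),
                           beta = new_param(numeric(C))))
}

#' @export
nn_forward.layer_groupnorm <- function(mod, x, train = FALSE) {
  d <- dim(x)
  HW <- d[1] * d[2]
  C <- mod$C
  G <- mod$groups
  Cg <- C %/% G
  N <- d[4]
  # group means/vars: reshape to (HW*Cg, G*N) columns
  xm <- matrix(x, HW * Cg)
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  ivar <- 1 / sqrt(v + mod$eps)
  xhat <- (xm - rep(mu, each = HW * Cg)) * rep(ivar, each = HW * Cg)
  dim(xhat) <- d
  if (train) {
    mod$cache$xhat <- xhat
    mod$cache$ivar <- ivar
    mod$cache$m <- HW * Cg
  }
  xhat * bcast_c(mod$params$gamma$v, HW) + bcast_c(mod$params$beta$v, HW)
}

#' @export
nn_backward.layer_groupnorm <- function(mod, dy) {
  d <- dim(dy)
  HW <- d[1] * d[2]
  C <- mod$C
  Cg <- C %/% mod$groups
  xhat <- mod$cache$xhat
  m <- mod$cache$m
  dxhat <- dy * bcast_c(mod$params$gamma$v, HW)
  dxm <- matrix(dxhat, m)
  xhm <- matrix(xhat, m)
  s1 <- colMeans(dxm)
  s2 <- colMeans(dxm * xhm)
  dx <- rep(mod$cache$ivar, each = m) *
    (dxm - rep(s1, each = m) - xhm * rep(s2, each = m))
  dim(dx) <- d
  mod$params$gamma$g <- mod$params$gamma$g + channel_sum(dy * xhat, C)
  mod$params$beta$g <- mod$params$beta$g + channel_sum(dy, C)
  dx
}

#' 2x2 max-pooling layer (stride 2)
#' @export
layer_maxpool2 <- function() new_module("layer_maxpool2")

#' @export
nn_forward.layer_maxpool2 <- function(mod, x, train = FALSE) {
  out <- cpp_maxpool2_fwd(x)
  if (train) {
    mod$cache$idx <- out$idx
    mod$cache$in_dim <- dim(x)
  }
  out$y
}

#' @export
nn_backward.layer_maxpool2 <- function(mod, dy) {
  cpp_maxpool2_bwd(dy, mod$cache$idx, as.integer(mod$cache$in_dim))
}

#' Decoder upsampling layer (doubles H and W, halves channels)
#'
#' Either bilinear interpolation followed by a channel-halving 1x1
#' convolution (default), or a learnable 2x2 stride-2 transposed convolution.
#'
#' @param in_ch Input channel count (must be even; output has `in_ch / 2`).
#' @param mode `"bilinear"` or `"transposed"`.
#' @export
layer_upsample <- function(in_ch, mode = c("bilinear", "transposed")) {
  mode <- match.arg(mode)
  stop_if_not(in_ch %% 2 == 0, "upsample input channels must be even")
  out_ch <- as.integer(in_ch %/% 2)
  if (mode == "bilinear") {
    new_module("layer_upsample_bilinear", in_ch = as.integer(in_ch),
               out_ch = out_ch,
               modules = list(proj = layer_conv2d(in_ch, out_ch, kernel = 1L)))
  } else {
    w <- init_he(c(2, 2, in_ch, out_ch), fan_in = 4 * in_ch)
    new_module("layer_upsample_transposed", in_ch = as.integer(in_ch),
               out_ch = out_ch,
               params = list(w = new_param(w), b = new_param(numeric(out_ch))))
  }
}

#' @export
nn_forward.layer_upsample_bilinear <- function(mod, x, train = FALSE) {
  d <- dim(x)
  up <- cpp_resize_bilinear_fwd(x, 2L * d[1], 2L * d[2])
  if (train) mod$cache$in_dim <- d
  nn_forward(mod$modules$proj, up, train)
}

#' @export
nn_backward.layer_upsample_bilinear <- function(mod, dy) {
  dup <- nn_backward(mod$modules$proj, dy)
  d <- mod$cache$in_dim
  cpp_resize_bilinear_bwd(dup, d[1], d[2])
}

#' @export
nn_forward.layer_upsample_transposed <- function(mod, x, train = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; Ci <- d[3]; N <- d[4]
  Co <- mod$out_ch
  y <- array(0, c(2 * H, 2 * W, Co, N))
  for (n in seq_len(N)) {
    Xn <- matrix(x[, , , n], H * W, Ci)
    for (di in 1:2) for (dj in 1:2) {
      Wm <- matrix(mod$params$w$v[di, dj, , ], Ci, Co)
      Ym <- Xn %*% Wm
      Ym <- sweep(Ym, 2, mod$params$b$v / 4, "+")
      y[seq(di, 2 * H, 2), seq(dj, 2 * W, 2), , n] <- array(Ym, c(H, W, Co))
    }
  }
  if (train) mod$cache$x <- x
  y
}

#' @export
nn_backward.layer_upsample_transposed <- function(mod, dy) {
  x <- mod$cache$x
  d <- dim(x)
  H <- d[1]; W <- d[2]; Ci <- d[3]; N <- d[4]
  Co <- mod$out_ch
  dx <- array(0, d)
  for (n in seq_len(N)) {
    Xn <- matrix(x[, , , n], H * W, Ci)
    dXn <- matrix(0, H * W, Ci)
    for (di in 1:2) for (dj in 1:2) {
      Wm <- matrix(mod$params$w$v[di, dj, , ], Ci, Co)
      dYm <- matrix(dy[seq(di, 2 * H, 2), seq(dj, 2 * W, 2), , n], H * W, Co)
      mod$params$w$g[di, dj, , ] <- mod$params$w$g[di, dj, , ] +
        crossprod(Xn, dYm)
      mod$params$b$g <- mod$params$b$g + colSums(dYm) / 4
      dXn <- dXn + dYm %*% t(Wm)
    }
    dx[, , , n] <- array(dXn, c(H, W, Ci))
  }
  dx
}
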