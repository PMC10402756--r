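# The per-stage composite blocks.  All preserve (H, W, C, N): the residual
# identity path requires in_channels == out_channels, and every convolution
# uses "same" padding.

block_branch <- function(C, dilation, kernel = 3L) {
  list(conv1 = layer_conv2d(C, C, kernel, dilation),
       relu1 = layer_relu(),
       conv2 = layer_conv2d(C, C, kernel, dilation))
}

check_block_channels <- function(mod, x) {
  if (dim(x)[3] != mod$channels)
    stop(sprintf("channel mismatch: block built for %d channels, input has %d",
                 mod$channels, dim(x)[3]), call. = FALSE)
}

#' DCTR block: dilated convolutions + transformer on a residual path
#'
#' The input is split into two parallel parts.  The first passes through a
#' dilated convolution, ReLU, a second dilated convolution, and a transformer
#' layer (self-attention over the pooled token grid, providing global
#' context); the second is the identity.  The two are summed and passed
#' through a final ReLU, so the output is elementwise non-negative and has
#' the shape of the input.
#'
#' @param channels Channel count (preserved).
#' @param dilation Dilation rate of both convolutions (default 2).
#' @param n_heads,mlp_ratio,token_grid Transformer settings, see
#'   [transformer_spec()].
#' @param with_transformer If `FALSE` the transformer layer is omitted
#'   (used when the network restricts transformers to selected stages).
#' @return A module; apply with [nn_forward()].
#' @export
dctr_block <- function(channels, dilation = 2L, n_heads = 8L, mlp_ratio = 4L,
                       token_grid = 16L, with_transformer = TRUE) {
  mods <- block_branch(channels, dilation)
  if (with_transformer)
    mods$gc <- layer_global_context(channels, n_heads, mlp_ratio, token_grid)
  mods$relu_out <- layer_relu()
  new_module("dctr_block", channels = as.integer(channels),
             dilation = as.integer(dilation),
             with_transformer = with_transformer, modules = mods)
}

#' @export
nn_forward.dctr_block <- function(mod, x, train = FALSE) {
  check_block_channels(mod, x)
  m <- mod$modules
  b <- nn_forward(m$conv1, x, train)
  b <- nn_forward(m$relu1, b, train)
  b <- nn_forward(m$conv2, b, train)
  if (mod$with_transformer) b <- nn_forward(m$gc, b, train)
  nn_forward(m$relu_out, b + x, train)
}

#' @export
nn_backward.dctr_block <- function(mod, dy) {
  m <- mod$modules
  ds <- nn_backward(m$relu_out, dy)   # gradient at (branch + identity)
  db <- ds
  if (mod$with_transformer) db <- nn_backward(m$gc, db)
  db <- nn_backward(m$conv2, db)
  db <- nn_backward(m$relu1, db)
  db <- nn_backward(m$conv1, db)
  db + ds
}

#' Dilated residual block (no transformer)
#'
#' Branch: dilated convolution, ReLU, dilated convolution, ReLU; identity on
#' the second path; output is the plain sum of the two (no activation after
#' the add, so outputs can be negative where the input is).
#'
#' @inheritParams dctr_block
#' @export
dilated_residual_block <- function(channels, dilation = 2L) {
  mods <- block_branch(channels, dilation)
  mods$relu2 <- layer_relu()
  new_module("dilated_residual_block", channels = as.integer(channels),
             dilation = as.integer(dilation), modules = mods)
}

#' @export
nn_forward.dilated_residual_block <- function(mod, x, train = FALSE) {
  check_block_channels(mod, x)
  m <- mod$modules
  b <- nn_forward(m$conv1, x, train)
  b <- nn_forward(m$relu1, b, train)
  b <- nn_forward(m$conv2, b, train)
  b <- nn_forward(m$relu2, b, train)
  b + x
}

#' @export
nn_backward.dilated_residual_block <- function(mod, dy) {
  m <- mod$modules
  db <- nn_backward(m$relu2, dy)
  db <- nn_backward(m$conv2, db)
  db <- nn_backward(m$relu1, db)
  db <- nn_backward(m$conv1, db)
  db + dy
}

#' Residual transformer block
#'
#' Structurally a [dctr_block()] with both convolutions at dilation rate 1
#' (plain 3x3): conv, ReLU, conv, transformer layer on the branch, identity
#' on the other path, sum, final ReLU.
#'
#' @inheritParams dctr_block
#' @export
residual_transformer_block <- function(channels, n_heads = 8L, mlp_ratio = 4L,
                                       token_grid = 16L) {
  blk <- dctr_block(channels, dilation = 1L, n_heads = n_heads,
                    mlp_ratio = mlp_ratio, token_grid = token_grid)
  class(blk) <- c("residual_transformer_block", class(blk))
  blk
}

#' Plain double-convolution block (baseline U-Net stage body)
#'
#' Two 3x3 convolutions each followed by ReLU; no residual path, no
#' transformer, channels preserved.
#'
#' @param channels Channel count.
#' @export
plain_block <- function(channels) {
  mods <- block_branch(channels, dilation = 1L)
  mods$relu2 <- layer_relu()
  new_module("plain_block", channels = as.integer(channels), modules = mods)
}

#' @export
nn_forward.plain_block <- function(mod, x, train = FALSE) {
  check_block_channels(mod, x)
  m <- mod$modules
  b <- nn_forward(m$conv1, x, train)
  b <- nn_forward(m$relu1, b, train)
  b <- nn_forward(m$conv2, b, train)
  nn_forward(m$relu2, b, train)
}

#' @export
nn_backward.plain_block <- function(mod, dy) {
  m <- mod$modules
  db <- nn_backward(m$relu2, dy)
  db <- nn_backward(m$conv2, db)
  db <- nn_backward(m$relu1, db)
  nn_backward(m$conv1, db)
}
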