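# Token-sequence layers.  Token arrays are (T, E, N): T tokens of embedding
# width E per batch sample.  Tokens come from flattening a spatial grid; the
# block applies no positional encoding, so token order is purely positional
# bookkeeping.

#' Transformer block configuration
#'
#' @param embed_dim Embedding width (token channel count); must be divisible
#'   by `n_heads`.
#' @param n_heads Number of self-attention heads (default 8).
#' @param mlp_hidden_dim Hidden width of the per-token MLP
#'   (default `4 * embed_dim`).
#' @param token_grid Maximum side length of the token grid a feature map is
#'   average-pooled to before attention (default 16, i.e. at most 256 tokens).
#' @return A `transformer_spec` list.
#' @export
transformer_spec <- function(embed_dim, n_heads = 8L,
                             mlp_hidden_dim = 4L * embed_dim,
                             token_grid = 16L) {
  stop_if_not(embed_dim >= 1 && n_heads >= 1 && mlp_hidden_dim >= 1 &&
                token_grid >= 1, "transformer dims must be positive")
  if (embed_dim %% n_heads != 0)
    stop(sprintf("embed_dim (%d) must be divisible by n_heads (%d)",
                 embed_dim, n_heads), call. = FALSE)
  structure(list(embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 mlp_hidden_dim = as.integer(mlp_hidden_dim),
                 token_grid = as.integer(token_grid)),
            class = "transformer_spec")
}

as_token_array <- function(t) {
  d <- dim(t)
  if (is.null(d)) stop("tokens must be a (T, E) matrix or (T, E, N) array",
                       call. = FALSE)
  if (length(d) == 2) dim(t) <- c(d, 1L)
  else if (length(d) != 3) stop("tokens must be (T, E, N)", call. = FALSE)
  t
}

#' Flatten a feature map into a token sequence
#'
#' Each spatial position becomes one token with the channel vector as its
#' embedding; `grid_shape` records the source grid for the inverse mapping.
#'
#' @param x Feature map `(H, W, C, N)`.
#' @return List with `tokens` `(H*W, C, N)` and `grid_shape` `c(H, W)`.
#' @export
tokens_from_grid <- function(x) {
  x <- as_feature_map(x)
  d <- dim(x)
  tokens <- x
  dim(tokens) <- c(d[1] * d[2], d[3], d[4])
  list(tokens = tokens, grid_shape = d[1:2])
}

#' Reshape a token sequence back onto its spatial grid
#' @param tokens Token array `(T, E, N)` with `T = prod(grid_shape)`.
#' @param grid_shape Integer vector `c(H, W)`.
#' @return Feature map `(H, W, E, N)`.
#' @export
tokens_to_grid <- function(tokens, grid_shape) {
  tokens <- as_token_array(tokens)
  d <- dim(tokens)
  stop_if_not(d[1] == prod(grid_shape),
              "token count %d does not match grid %dx%d",
              d[1], grid_shape[1], grid_shape[2])
  dim(tokens) <- c(grid_shape[1], grid_shape[2], d[2], d[3])
  tokens
}

# ---- layer norm over the embedding dim, per token -------------------------

layer_layernorm <- function(E, eps = 1e-5) {
  new_module("layer_layernorm", E = as.integer(E), eps = eps,
             params = list(gamma = new_param(rep(1, E)),
                           beta = new_param(numeric(E))))
}

#' @export
nn_forward.layer_layernorm <- function(mod, x, train = FALSE) {
  d <- dim(x)
  Tn <- d[1]; E <- d[2]; N <- d[3]
  gm <- matrix(mod$params$gamma$v, Tn, E, byrow = TRUE)
  bm <- matrix(mod$params$beta$v, Tn, E, byrow = TRUE)
  y <- array(0, d)
  if (train) {
    mod$cache$xhat <- array(0, d)
    mod$cache$inv <- matrix(0, Tn, N)
  }
  for (n in seq_len(N)) {
    X <- matrix(x[, , n], Tn, E)
    mu <- rowMeans(X)
    xc <- X - mu
    inv <- 1 / sqrt(rowMeans(xc^2) + mod$eps)
    xhat <- xc * inv
    y[, , n] <- xhat * gm + bm
    if (train) {
      mod$cache$xhat[, , n] <- xhat
      mod$cache$inv[, n] <- inv
    }
  }
  y
}

#' @export
nn_backward.layer_layernorm <- function(mod, dy) {
  d <- dim(dy)
  Tn <- d[1]; E <- d[2]; N <- d[3]
  gm <- matrix(mod$params$gamma$v, Tn, E, byrow = TRUE)
  dx <- array(0, d)
  for (n in seq_len(N)) {
    dyn <- matrix(dy[, , n], Tn, E)
    xhat <- matrix(mod$cache$xhat[, , n], Tn, E)
    inv <- mod$cache$inv[, n]
    dxhat <- dyn * gm
    dx[, , n] <- inv * (dxhat - rowMeans(dxhat) -
                          xhat * rowMeans(dxhat * xhat))
    mod$params$gamma$g <- mod$params$gamma$g + colSums(dyn * xhat)
    mod$params$beta$g <- mod$params$beta$g + colSums(dyn)
  }
  dx
}

# ---- multi-head self-attention --------------------------------------------

layer_msa <- function(E, heads) {
  stop_if_not(E %% heads == 0, "embed_dim must be divisible by n_heads")
  p <- function() new_param(init_xavier(c(E, E), E, E))
  new_module("layer_msa", E = as.integer(E), heads = as.integer(heads),
             params = list(wq = p(), wk = p(), wv = p(), wo = p(),
                           bq = new_param(numeric(E)),
                           bk = new_param(numeric(E)),
                           bv = new_param(numeric(E)),
                           bo = new_param(numeric(E))))
}

#' @export
nn_forward.layer_msa <- function(mod, x, train = FALSE) {
  d <- dim(x)
  Tn <- d[1]; E <- d[2]; N <- d[3]
  h <- mod$heads
  dh <- E %/% h
  p <- mod$params
  y <- array(0, d)
  if (train) mod$cache$per_n <- vector("list", N)
  for (n in seq_len(N)) {
    X <- matrix(x[, , n], Tn, E)
    Q <- sweep(X %*% p$wq$v, 2, p$bq$v, "+")
    K <- sweep(X %*% p$wk$v, 2, p$bk$v, "+")
    V <- sweep(X %*% p$wv$v, 2, p$bv$v, "+")
    O <- matrix(0, Tn, E)
    Ps <- vector("list", h)
    for (hh in seq_len(h)) {
      cols <- (hh - 1) * dh + seq_len(dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) /
        sqrt(dh)
      S <- S - apply(S, 1, max)
      P <- exp(S)
      P <- P / rowSums(P)
      O[, cols] <- P %*% V[, cols, drop = FALSE]
      Ps[[hh]] <- P
    }
    y[, , n] <- sweep(O %*% p$wo$v, 2, p$bo$v, "+")
    if (train)
      mod$cache$per_n[[n]] <- list(X = X, Q = Q, K = K, V = V, O = O, P = Ps)
  }
  y
}

#' @export
nn_backward.layer_msa <- function(mod, dy) {
  d <- dim(dy)
  Tn <- d[1]; E <- d[2]; N <- d[3]
  h <- mod$heads
  dh <- E %/% h
  p <- mod$params
  dx <- array(0, d)
  for (n in seq_len(N)) {
    cc <- mod$cache$per_n[[n]]
    dyn <- matrix(dy[, , n], Tn, E)
    p$wo$g <- p$wo$g + crossprod(cc$O, dyn)
    p$bo$g <- p$bo$g + colSums(dyn)
    dO <- tcrossprod(dyn, p$wo$v)
    dQ <- matrix(0, Tn, E); dK <- matrix(0, Tn, E); dV <- matrix(0, Tn, E)
    for (hh in seq_len(h)) {
      cols <- (hh - 1) * dh + seq_len(dh)
      P <- cc$P[[hh]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- cc$V[, cols, drop = FALSE]
      dP <- tcrossprod(dOh, Vh)
      dV[, cols] <- crossprod(P, dOh)
      dS <- P * (dP - rowSums(dP * P))
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    p$wq$g <- p$wq$g + crossprod(cc$X, dQ)
    p$wk$g <- p$wk$g + crossprod(cc$X, dK)
    p$wv$g <- p$wv$g + crossprod(cc$X, dV)
    p$bq$g <- p$bq$g + colSums(dQ)
    p$bk$g <- p$bk$g + colSums(dK)
    p$bv$g <- p$bv$g + colSums(dV)
    dx[, , n] <- tcrossprod(dQ, p$wq$v) + tcrossprod(dK, p$wk$v) +
      tcrossprod(dV, p$wv$v)
  }
  dx
}

# ---- per-token MLP (linear -> GELU -> linear) ------------------------------

layer_token_mlp <- function(E, hidden) {
  new_module("layer_token_mlp", E = as.integer(E), hidden = as.integer(hidden),
             params = list(w1 = new_param(init_xavier(c(E, hidden), E, hidden)),
                           b1 = new_param(numeric(hidden)),
                           w2 = new_param(init_xavier(c(hidden, E), hidden, E)),
                           b2 = new_param(numeric(E))))
}

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

#' @export
nn_forward.layer_token_mlp <- function(mod, x, train = FALSE) {
  d <- dim(x)
  Tn <- d[1]; N <- d[3]
  p <- mod$params
  y <- array(0, d)
  if (train) mod$cache$per_n <- vector("list", N)
  for (n in seq_len(N)) {
    X <- matrix(x[, , n], Tn, d[2])
    H1 <- sweep(X %*% p$w1$v, 2, p$b1$v, "+")
    A <- gelu(H1)
    y[, , n] <- sweep(A %*% p$w2$v, 2, p$b2$v, "+")
    if (train) mod$cache$per_n[[n]] <- list(X = X, H1 = H1, A = A)
  }
  y
}

#' @export
nn_backward.layer_token_mlp <- function(mod, dy) {
  d <- dim(dy)
  Tn <- d[1]; N <- d[3]
  p <- mod$params
  dx <- array(0, d)
  for (n in seq_len(N)) {
    cc <- mod$cache$per_n[[n]]
    dyn <- matrix(dy[, , n], Tn, d[2])
    p$w2$g <- p$w2$g + crossprod(cc$A, dyn)
    p$b2$g <- p$b2$g + colSums(dyn)
    dA <- tcrossprod(dyn, p$w2$v)
    dH1 <- dA * gelu_grad(cc$H1)
    p$w1$g <- p$w1$g + crossprod(cc$X, dH1)
    p$b1$g <- p$b1$g + colSums(dH1)
    dx[, , n] <- tcrossprod(dH1, p$w1$v)
  }
  dx
}

# ---- the pre-norm transformer block ----------------------------------------

#' Pre-norm transformer block over a token sequence
#'
#' Computes `x' = MSA(LN(x)) + x` then `out = MLP(LN(x')) + x'`: layer
#' normalization is applied before the multi-head self-attention and before
#' the per-token MLP, and each unit is wrapped in a residual add.  No
#' positional encoding and no dropout are used.  With all projection weights
#' and biases zero the block is an exact identity (the residual paths carry
#' the input through unchanged).
#'
#' @param spec A [transformer_spec()].
#' @return A module applied to `(T, E, N)` token arrays via [nn_forward()].
#' @export
transformer_block <- function(spec) {
  stop_if_not(inherits(spec, "transformer_spec"),
              "spec must be a transformer_spec")
  E <- spec$embed_dim
  new_module("transformer_block", spec = spec,
             modules = list(ln1 = layer_layernorm(E),
                            msa = layer_msa(E, spec$n_heads),
                            ln2 = layer_layernorm(E),
                            mlp = layer_token_mlp(E, spec$mlp_hidden_dim)))
}

#' @export
nn_forward.transformer_block <- function(mod, x, train = FALSE) {
  x <- as_token_array(x)
  if (dim(x)[2] != mod$spec$embed_dim)
    stop(sprintf("token embed dim %d does not match spec embed_dim %d",
                 dim(x)[2], mod$spec$embed_dim), call. = FALSE)
  m <- mod$modules
  x1 <- x + nn_forward(m$msa, nn_forward(m$ln1, x, train), train)
  x1 + nn_forward(m$mlp, nn_forward(m$ln2, x1, train), train)
}

#' @export
nn_backward.transformer_block <- function(mod, dy) {
  m <- mod$modules
  dx1 <- dy + nn_backward(m$ln2, nn_backward(m$mlp, dy))
  dx1 + nn_backward(m$ln1, nn_backward(m$msa, dx1))
}

# ---- global-context layer: transformer applied inside a spatial block ------

# Pools the feature map onto at most token_grid x token_grid tokens (average
# pooling by an integer factor), runs the transformer block, and adds the
# bilinearly-upsampled attention correction (block output minus block input)
# back onto the full-resolution map.  Zero projection weights therefore make
# the layer an exact identity, matching the residual reading of the block.
layer_global_context <- function(channels, n_heads = 8L,
                                 mlp_ratio = 4L, token_grid = 16L) {
  heads <- n_heads
  while (channels %% heads != 0) heads <- heads - 1L  # largest feasible <= n_heads
  spec <- transformer_spec(channels, heads, mlp_ratio * channels, token_grid)
  new_module("layer_global_context", channels = as.integer(channels),
             token_grid = as.integer(token_grid),
             modules = list(tf = transformer_block(spec)))
}

#' @export
nn_forward.layer_global_context <- function(mod, x, train = FALSE) {
  d <- dim(x)
  f <- 1L
  while (max(d[1], d[2]) / f > mod$token_grid) f <- 2L * f
  stop_if_not(d[1] %% f == 0 && d[2] %% f == 0,
              "feature-map sides must be divisible by the pooling factor %d", f)
  pooled <- if (f > 1) cpp_avgpool_fwd(x, f) else x
  tk <- tokens_from_grid(pooled)
  out <- nn_forward(mod$modules$tf, tk$tokens, train)
  delta <- tokens_to_grid(out - tk$tokens, tk$grid_shape)
  up <- if (f > 1) cpp_resize_bilinear_fwd(delta, d[1], d[2]) else delta
  if (train) {
    mod$cache$f <- f
    mod$cache$grid <- tk$grid_shape
    mod$cache$in_dim <- d
  }
  x + up
}

#' @export
nn_backward.layer_global_context <- function(mod, dy) {
  f <- mod$cache$f
  grid <- mod$cache$grid
  ddelta <- if (f > 1) cpp_resize_bilinear_bwd(dy, grid[1], grid[2]) else dy
  dtok <- ddelta
  dim(dtok) <- c(grid[1] * grid[2], dim(ddelta)[3], dim(ddelta)[4])
  dpooled_tok <- nn_backward(mod$modules$tf, dtok) - dtok
  dpooled <- tokens_to_grid(dpooled_tok, grid)
  dx_pool <- if (f > 1) cpp_avgpool_bwd(dpooled, f) else dpooled
  dy + dx_pool
}
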