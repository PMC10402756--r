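# Independent oracles and small fixture builders shared across tests.

# direct sliding-window convolution with explicit zero insertion: the
# quadruple-loop reference for the compiled dilated convolution
naive_dilated_conv <- function(x, w, b, dil) {
  H <- dim(x)[1]; W <- dim(x)[2]; Ci <- dim(x)[3]; N <- dim(x)[4]
  K <- dim(w)[1]; Co <- dim(w)[4]
  pad <- (K - 1) * dil / 2
  y <- array(0, c(H, W, Co, N))
  for (n in seq_len(N)) for (co in seq_len(Co)) for (i in seq_len(H))
    for (j in seq_len(W)) {
      s <- b[co]
      for (ci in seq_len(Ci)) for (ki in seq_len(K)) for (kj in seq_len(K)) {
        ii <- i + (ki - 1) * dil - pad
        jj <- j + (kj - 1) * dil - pad
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
          s <- s + x[ii, jj, ci, n] * w[ki, kj, ci, co]
      }
      y[i, j, co, n] <- s
    }
  y
}

# central finite differences of sum(f(x) * dy) at a few entries of x
numeric_input_grad <- function(f, x, dy, idx, h = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (sum(f(xp) * dy) - sum(f(xm) * dy)) / (2 * h)
  }, numeric(1))
}

# set every parameter of a module tree (weights and biases) to zero
zero_all_params <- function(mod) {
  for (p in nn_parameters(mod)) p$v <- p$v * 0
  invisible(mod)
}

bm <- function(grid, spacing = c(1, 1)) binary_mask(grid, spacing)

# reference GELU used by the closed-form transformer check
gelu_ref <- function(x) x * pnorm(x)

random_mask <- function(H, W, p_fg = 0.4) {
  repeat {
    m <- matrix(runif(H * W) < p_fg, H, W)
    if (any(m)) return(m)
  }
}

# four fixed small phantom slices used by training tests
overfit_cases <- function(size = 64L, n = 4L, seed = 11L) {
  spec <- phantom_spec(image_size = size, slices_per_patient = n, seed = seed)
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(spec, seed = 100L + i)
    list(image = ph$image, mask = ph$mask)
  })
}

tiny_net_config <- function(variant = "dctr", size = 32L)
  network_config(variant, input_size = size, base_channels = 4L,
                 n_heads = 4L, token_grid = 8L)

tiny_train_config <- function(epochs = 2L, seed = 2L)
  train_config(epochs = epochs, batch_size = 4L, seed = seed,
               lr_initial = 1e-3, lr_after = 1e-3, lr_switch_epoch = 0L)
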