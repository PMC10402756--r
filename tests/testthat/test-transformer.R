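test_that("transformer spec validates the head divisibility", {
  expect_error(transformer_spec(10, 4), "divisible")
  sp <- transformer_spec(8, 4)
  expect_identical(sp$mlp_hidden_dim, 32L)
})

test_that("zero projection weights make the block an exact passthrough", {
  set.seed(1)
  blk <- transformer_block(transformer_spec(8, 2))
  zero_all_params(blk)
  # restore the layer-norm scale so LN itself still runs (its output is then
  # annihilated by the zero projections)
  blk$modules$ln1$params$gamma$v <- rep(1, 8)
  blk$modules$ln2$params$gamma$v <- rep(1, 8)
  x <- array(rnorm(5 * 8 * 2), c(5, 8, 2))
  expect_identical(nn_forward(blk, x), x)
})

test_that("a single token attends only to itself", {
  set.seed(3)
  blk <- transformer_block(transformer_spec(6, 2))
  x <- array(rnorm(1 * 6 * 1), c(1, 6, 1))
  m <- blk$modules
  # closed form: softmax over one key is 1, so MSA(LN(x)) is the value
  # projection of LN(x) followed by the output projection
  ln1 <- nn_forward(m$ln1, x)
  v <- matrix(ln1[, , 1], 1, 6) %*% m$msa$params$wv$v +
    matrix(m$msa$params$bv$v, 1)
  msa <- v %*% m$msa$params$wo$v + matrix(m$msa$params$bo$v, 1)
  x1 <- x + array(msa, c(1, 6, 1))
  ln2 <- nn_forward(m$ln2, x1)
  h <- gelu_ref(matrix(ln2[, , 1], 1, 6) %*% m$mlp$params$w1$v +
                  matrix(m$mlp$params$b1$v, 1))
  expected <- x1 + array(h %*% m$mlp$params$w2$v +
                           matrix(m$mlp$params$b2$v, 1), c(1, 6, 1))
  expect_equal(nn_forward(blk, x), expected, tolerance = 1e-12)
})

test_that("the block commutes with token permutations (no positions)", {
  set.seed(8)
  blk <- transformer_block(transformer_spec(8, 4))
  x <- array(rnorm(10 * 8 * 2), c(10, 8, 2))
  perm <- sample(10)
  y <- nn_forward(blk, x)
  yp <- nn_forward(blk, x[perm, , , drop = FALSE])
  expect_equal(yp[order(perm), , , drop = FALSE], y, tolerance = 1e-12)
})

test_that("block output is finite and shape-preserving", {
  set.seed(2)
  blk <- transformer_block(transformer_spec(8, 2))
  x <- array(rnorm(12 * 8 * 3), c(12, 8, 3))
  y <- nn_forward(blk, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  expect_error(nn_forward(blk, array(0, c(3, 4, 1))), "embed dim")
})

test_that("transformer block gradients match finite differences", {
  set.seed(12)
  blk <- transformer_block(transformer_spec(4, 2))
  x <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  y <- nn_forward(blk, x, train = TRUE)
  dy <- array(rnorm(length(y)), dim(y))
  dx <- nn_backward(blk, dy)
  idx <- sample(length(x), 10)
  ng <- numeric_input_grad(function(z) nn_forward(blk, z, train = TRUE),
                           x, dy, idx)
  expect_equal(dx[idx], ng, tolerance = 1e-4)
  # and one attention projection parameter
  p <- nn_parameters(blk)[["msa.layer_msa.wq"]]
  pidx <- sample(length(p$v), 6)
  ngp <- vapply(pidx, function(i) {
    v0 <- p$v
    p$v[i] <- v0[i] + 1e-5
    up <- sum(nn_forward(blk, x, train = TRUE) * dy)
    p$v[i] <- v0[i] - 1e-5
    dn <- sum(nn_forward(blk, x, train = TRUE) * dy)
    p$v <- v0
    (up - dn) / 2e-5
  }, numeric(1))
  expect_equal(p$g[pidx], ngp, tolerance = 1e-4)
})

test_that("token grid round-trip is the identity", {
  set.seed(6)
  x <- array(rnorm(4 * 6 * 3 * 2), c(4, 6, 3, 2))
  tk <- tokens_from_grid(x)
  expect_identical(dim(tk$tokens), c(24L, 3L, 2L))
  expect_identical(tokens_to_grid(tk$tokens, tk$grid_shape), x)
  expect_error(tokens_to_grid(tk$tokens, c(5, 5)), "does not match")
})
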