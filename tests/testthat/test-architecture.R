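test_that("configuration validates variant names and divisibility", {
  expect_error(network_config("resnet"), "unet, unet_dr, unet_rt, dctr")
  expect_error(network_config("dctr", input_size = 100), "divisible")
  expect_error(make_variant("swin"), "unknown variant")
  expect_identical(make_variant("dctr")$variant, "dctr")
  expect_identical(make_variant("unet_dr", base_channels = 8L)$base_channels,
                   8L)
})

test_that("every variant maps (H, W, 1, N) to (H, W, 1, N) in (0, 1)", {
  set.seed(1)
  x <- array(rnorm(64 * 64 * 1 * 2), c(64, 64, 1, 2))
  for (v in c("unet", "unet_dr", "unet_rt", "dctr")) {
    net <- build_network(make_variant(v, input_size = 64L,
                                      base_channels = 8L), seed = 3)
    p <- nn_forward(net, x)
    expect_identical(dim(p), c(64L, 64L, 1L, 2L))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("variant factory swaps only the per-stage block type", {
  net_u <- build_network(make_variant("unet", input_size = 32L,
                                      base_channels = 4L), seed = 1)
  net_dr <- build_network(make_variant("unet_dr", input_size = 32L,
                                       base_channels = 4L), seed = 1)
  net_d <- build_network(make_variant("dctr", input_size = 32L,
                                      base_channels = 4L, n_heads = 4L),
                         seed = 1)
  nm_u <- names(nn_parameters(net_u))
  nm_dr <- names(nn_parameters(net_dr))
  nm_d <- names(nn_parameters(net_d))
  # no attention parameters outside the transformer variants
  expect_length(grep("msa|mlp|layernorm", nm_u), 0)
  expect_length(grep("msa|mlp|layernorm", nm_dr), 0)
  expect_gt(length(grep("msa", nm_d)), 0)
  # dilated convolutions present exactly in the dilated variants
  has_dilated <- function(net) any(vapply(module_list(net), function(m)
    inherits(m, "layer_conv2d") && m$dilation > 1, logical(1)))
  expect_false(has_dilated(net_u))
  expect_true(has_dilated(net_dr))
  expect_true(has_dilated(net_d))
  # a plain U-Net is strictly smaller than the DCTR model at equal width
  expect_lt(parameter_count(net_u), parameter_count(net_d))
})

test_that("decoder channel counts match the encoder at every skip merge", {
  net <- build_network(make_variant("dctr", input_size = 64L,
                                    base_channels = 8L), seed = 2)
  S <- net$config$n_stages
  for (i in seq_len(S)) {
    enc <- net$modules[[paste0("enc", i, "_conv")]]
    dec <- net$modules[[paste0("dec", i, "_conv")]]
    up <- net$modules[[paste0("dec", i, "_up")]]
    expect_identical(dec$out_ch, enc$out_ch)      # "restored" rule
    expect_identical(dec$in_ch, 2L * enc$out_ch)  # concat of up + skip
    expect_identical(up$out_ch, enc$out_ch)       # halving on upsample
  }
  expect_identical(net$modules$bottom_conv$out_ch,
                   16L * net$config$base_channels)
})

test_that("forward pass is deterministic and positionally unbiased", {
  set.seed(4)
  net <- build_network(make_variant("dctr", input_size = 32L,
                                    base_channels = 4L, n_heads = 4L),
                       seed = 5)
  # all-zero input: no positional encoding anywhere, so the map is constant
  pz <- nn_forward(net, array(0, c(32, 32, 1, 1)))
  expect_lt(max(pz) - min(pz), 1e-12)
  # identical inputs in one batch give identical output slices
  one <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  two <- array(c(one, one), c(32, 32, 1, 2))
  p2 <- nn_forward(net, two)
  expect_identical(p2[, , , 1], p2[, , , 2])
  # spatial-size mismatch is a shape error
  expect_error(nn_forward(net, array(0, c(64, 64, 1, 1))), "built for")
})

test_that("group normalization and transposed upsampling variants build", {
  set.seed(6)
  cfg <- network_config("dctr", input_size = 32L, base_channels = 4L,
                        n_heads = 4L, norm = "group",
                        upsample_mode = "transposed")
  net <- build_network(cfg, seed = 7)
  p <- nn_forward(net, array(rnorm(32 * 32), c(32, 32, 1, 1)))
  expect_identical(dim(p), c(32L, 32L, 1L, 1L))
  expect_true(all(is.finite(p)))
})

test_that("bottleneck-only transformer placement is honored", {
  cfg <- network_config("dctr", input_size = 32L, base_channels = 4L,
                        n_heads = 4L, transformer_stages = 5L)
  net <- build_network(cfg, seed = 1)
  nm <- names(nn_parameters(net))
  att <- grep("msa", nm, value = TRUE)
  expect_gt(length(att), 0)
  expect_true(all(grepl("^bottom_block", att)))
})

test_that("checkpoints round-trip to bit-identical predictions", {
  set.seed(8)
  net <- build_network(make_variant("dctr", input_size = 32L,
                                    base_channels = 4L, n_heads = 4L),
                       seed = 9)
  cases <- overfit_cases(size = 32L, n = 2L)
  train_network(net, cases, tiny_train_config(epochs = 1L))
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  p1 <- nn_forward(net, x)
  ck <- file.path(tempdir(), "ck.rds")
  save_checkpoint(net, ck)
  net2 <- load_checkpoint(ck)
  expect_identical(nn_forward(net2, x), p1)
  expect_error(load_checkpoint(file.path(tempdir(), "nope.rds")),
               "not found")
})
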