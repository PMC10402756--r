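VARIANTS <- c("unet", "unet_dr", "unet_rt", "dctr")

#' Network architecture configuration
#'
#' Full hyperparameter record for a U-shaped segmentation network: four
#' (by default) down-sampling stages, a bottom connection stage and four
#' up-sampling stages with skip connections.  The per-stage block is chosen
#' by `variant`: plain double convolutions (`"unet"`), dilated residual
#' blocks (`"unet_dr"`), residual transformer blocks (`"unet_rt"`), or the
#' full dilated-convolution transformer residual block (`"dctr"`).
#'
#' @param variant One of `"unet"`, `"unet_dr"`, `"unet_rt"`, `"dctr"`.
#' @param input_size Spatial input size, scalar or `c(H, W)`; each side must
#'   be divisible by `2^n_stages` (default 512).
#' @param in_channels Input channels (default 1, grayscale).
#' @param base_channels First-stage width (default 64); stages use
#'   `base_channels * c(1, 2, 4, 8)` with `16 * base_channels` at the bottom.
#' @param n_stages Number of down/up-sampling stages (default 4).
#' @param dilation_rate Dilation rate of the block convolutions (default 2).
#' @param n_heads,mlp_ratio,token_grid Transformer settings (see
#'   [transformer_spec()]); heads are reduced per stage to the largest
#'   divisor of the stage width not exceeding `n_heads`.
#' @param transformer_stages Stage indices (1..`n_stages` encoder stages,
#'   `n_stages + 1` = bottom) whose DCTR blocks contain the transformer
#'   layer; default all stages.  Set to `n_stages + 1` for a bottleneck-only
#'   transformer.
#' @param norm `"batch"` or `"group"` normalization after stage convolutions.
#' @param upsample_mode `"bilinear"` (interpolation + 1x1 convolution) or
#'   `"transposed"` (learnable 2x2 stride-2 transposed convolution).
#' @return A `network_config` list.
#' @export
network_config <- function(variant = "dctr", input_size = 512L,
                           in_channels = 1L, base_channels = 64L,
                           n_stages = 4L, dilation_rate = 2L, n_heads = 8L,
                           mlp_ratio = 4L, token_grid = 16L,
                           transformer_stages = NULL,
                           norm = c("batch", "group"),
                           upsample_mode = c("bilinear", "transposed")) {
  if (!variant %in% VARIANTS)
    stop(sprintf("unknown variant '%s'; valid variants are: %s", variant,
                 paste(VARIANTS, collapse = ", ")), call. = FALSE)
  norm <- match.arg(norm)
  upsample_mode <- match.arg(upsample_mode)
  if (length(input_size) == 1) input_size <- c(input_size, input_size)
  input_size <- as.integer(input_size)
  n_stages <- as.integer(n_stages)
  stop_if_not(base_channels >= 1, "base_channels must be >= 1")
  if (any(input_size %% 2^n_stages != 0))
    stop(sprintf("input size %dx%d must be divisible by 2^%d = %d",
                 input_size[1], input_size[2], n_stages, 2^n_stages),
         call. = FALSE)
  if (is.null(transformer_stages)) transformer_stages <- seq_len(n_stages + 1L)
  structure(list(variant = variant, input_size = input_size,
                 in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 n_stages = n_stages, dilation_rate = as.integer(dilation_rate),
                 n_heads = as.integer(n_heads), mlp_ratio = as.integer(mlp_ratio),
                 token_grid = as.integer(token_grid),
                 transformer_stages = as.integer(transformer_stages),
                 norm = norm, upsample_mode = upsample_mode),
            class = "network_config")
}

#' Build a network configuration for a named ablation variant
#'
#' Returns a [network_config()] that differs from the base configuration only
#' in the per-stage block type, for like-for-like ablation comparisons.
#'
#' @param name Variant name: `"unet"`, `"unet_dr"`, `"unet_rt"` or `"dctr"`.
#' @param ... Overrides passed to [network_config()].
#' @export
make_variant <- function(name, ...) network_config(variant = name, ...)

stage_block <- function(cfg, channels, stage) {
  switch(cfg$variant,
         unet = plain_block(channels),
         unet_dr = dilated_residual_block(channels, cfg$dilation_rate),
         unet_rt = residual_transformer_block(channels, cfg$n_heads,
                                              cfg$mlp_ratio, cfg$token_grid),
         dctr = dctr_block(channels, cfg$dilation_rate, cfg$n_heads,
                           cfg$mlp_ratio, cfg$token_grid,
                           with_transformer = stage %in% cfg$transformer_stages))
}

stage_norm <- function(cfg, channels) {
  if (cfg$norm == "batch") layer_batchnorm(channels) else
    layer_groupnorm(channels)
}

#' Build a segmentation network from a configuration
#'
#' Assembles the encoder (per stage: 3x3 convolution, normalization, ReLU,
#' variant block, 2x2 max pooling, with a skip tap after the block), the
#' bottom connection stage (3x3 convolution doubling channels, normalization,
#' ReLU, variant block), the decoder (per stage: channel-halving upsampling,
#' concatenation with the skip, 3x3 convolution halving channels back,
#' normalization, ReLU, variant block) and a 1x1 convolution + sigmoid output
#' head producing a 1-channel probability map of the input's spatial size.
#'
#' @param config A [network_config()].
#' @param seed Optional integer; when given, weight initialization is run
#'   under this seed (and the caller's RNG state is left untouched).
#' @return A `dctr_unet` module; apply with [nn_forward()], which returns
#'   per-pixel foreground probabilities in (0, 1).
#' @export
build_network <- function(config, seed = NULL) {
  stop_if_not(inherits(config, "network_config"),
              "config must be a network_config")
  builder <- function() {
    S <- config$n_stages
    ch <- as.integer(config$base_channels * 2^(seq_len(S) - 1))
    mods <- list()
    prev <- config$in_channels
    for (i in seq_len(S)) {
      mods[[paste0("enc", i, "_conv")]] <- layer_conv2d(prev, ch[i], 3L)
      mods[[paste0("enc", i, "_norm")]] <- stage_norm(config, ch[i])
      mods[[paste0("enc", i, "_relu")]] <- layer_relu()
      mods[[paste0("enc", i, "_block")]] <- stage_block(config, ch[i], i)
      mods[[paste0("enc", i, "_pool")]] <- layer_maxpool2()
      prev <- ch[i]
    }
    bot <- 2L * ch[S]
    mods$bottom_conv <- layer_conv2d(ch[S], bot, 3L)
    mods$bottom_norm <- stage_norm(config, bot)
    mods$bottom_relu <- layer_relu()
    mods$bottom_block <- stage_block(config, bot, S + 1L)
    for (i in rev(seq_len(S))) {
      above <- if (i == S) bot else ch[i + 1]
      mods[[paste0("dec", i, "_up")]] <- layer_upsample(above,
                                                        config$upsample_mode)
      mods[[paste0("dec", i, "_conv")]] <- layer_conv2d(2L * ch[i], ch[i], 3L)
      mods[[paste0("dec", i, "_norm")]] <- stage_norm(config, ch[i])
      mods[[paste0("dec", i, "_relu")]] <- layer_relu()
      mods[[paste0("dec", i, "_block")]] <- stage_block(config, ch[i], i)
    }
    mods$head <- layer_conv2d(ch[1], 1L, kernel = 1L)
    new_module("dctr_unet", config = config, channels = ch, modules = mods)
  }
  if (is.null(seed)) builder() else with_seed(seed, builder())
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' @export
nn_forward.dctr_unet <- function(mod, x, train = FALSE) {
  cfg <- mod$config
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2])
    stop(sprintf("input is %dx%d but the network was built for %dx%d",
                 d[1], d[2], cfg$input_size[1], cfg$input_size[2]),
         call. = FALSE)
  if (d[3] != cfg$in_channels)
    stop(sprintf("input has %d channels, expected %d", d[3], cfg$in_channels),
         call. = FALSE)
  m <- mod$modules
  S <- cfg$n_stages
  skips <- vector("list", S)
  for (i in seq_len(S)) {
    x <- nn_forward(m[[paste0("enc", i, "_conv")]], x, train)
    x <- nn_forward(m[[paste0("enc", i, "_norm")]], x, train)
    x <- nn_forward(m[[paste0("enc", i, "_relu")]], x, train)
    x <- nn_forward(m[[paste0("enc", i, "_block")]], x, train)
    skips[[i]] <- x
    x <- nn_forward(m[[paste0("enc", i, "_pool")]], x, train)
  }
  x <- nn_forward(m$bottom_conv, x, train)
  x <- nn_forward(m$bottom_norm, x, train)
  x <- nn_forward(m$bottom_relu, x, train)
  x <- nn_forward(m$bottom_block, x, train)
  for (i in rev(seq_len(S))) {
    x <- nn_forward(m[[paste0("dec", i, "_up")]], x, train)
    x <- concat_channels(x, skips[[i]])
    x <- nn_forward(m[[paste0("dec", i, "_conv")]], x, train)
    x <- nn_forward(m[[paste0("dec", i, "_norm")]], x, train)
    x <- nn_forward(m[[paste0("dec", i, "_relu")]], x, train)
    x <- nn_forward(m[[paste0("dec", i, "_block")]], x, train)
  }
  logits <- nn_forward(m$head, x, train)
  probs <- sigmoid(logits)
  if (train) mod$cache$probs <- probs
  probs
}

# Backward pass takes dL/dlogits (the gradient *before* the output sigmoid);
# the loss computes it analytically, which avoids the saturated-sigmoid
# precision loss of chaining through probabilities.
#' @export
nn_backward.dctr_unet <- function(mod, dlogits) {
  m <- mod$modules
  S <- mod$config$n_stages
  ch <- mod$channels
  dx <- nn_backward(m$head, dlogits)
  dskips <- vector("list", S)
  for (i in seq_len(S)) {
    dx <- nn_backward(m[[paste0("dec", i, "_block")]], dx)
    dx <- nn_backward(m[[paste0("dec", i, "_relu")]], dx)
    dx <- nn_backward(m[[paste0("dec", i, "_norm")]], dx)
    dx <- nn_backward(m[[paste0("dec", i, "_conv")]], dx)
    dup <- dx[, , seq_len(ch[i]), , drop = FALSE]
    dskips[[i]] <- dx[, , ch[i] + seq_len(ch[i]), , drop = FALSE]
    dx <- nn_backward(m[[paste0("dec", i, "_up")]], dup)
  }
  dx <- nn_backward(m$bottom_block, dx)
  dx <- nn_backward(m$bottom_relu, dx)
  dx <- nn_backward(m$bottom_norm, dx)
  dx <- nn_backward(m$bottom_conv, dx)
  for (i in rev(seq_len(S))) {
    dx <- nn_backward(m[[paste0("enc", i, "_pool")]], dx)
    dx <- dx + dskips[[i]]
    dx <- nn_backward(m[[paste0("enc", i, "_block")]], dx)
    dx <- nn_backward(m[[paste0("enc", i, "_relu")]], dx)
    dx <- nn_backward(m[[paste0("enc", i, "_norm")]], dx)
    dx <- nn_backward(m[[paste0("enc", i, "_conv")]], dx)
  }
  dx
}

#' Predict binary masks for a batch of images
#'
#' Runs the network in evaluation mode and thresholds the probability map.
#'
#' @param net A built network.
#' @param images Feature map `(H, W)`, `(H, W, C)` or `(H, W, C, N)`.
#' @param threshold Binarization threshold (default 0.5).
#' @return List with `prob` (the probability array `(H, W, 1, N)`) and
#'   `masks` (a list of N logical `H x W` matrices).
#' @export
predict_mask <- function(net, images, threshold = 0.5) {
  prob <- nn_forward(net, images, train = FALSE)
  d <- dim(prob)
  masks <- lapply(seq_len(d[4]), function(n)
    matrix(prob[, , 1, n] > threshold, d[1], d[2]))
  list(prob = prob, masks = masks)
}

# ---- checkpointing ---------------------------------------------------------

collect_state <- function(net) {
  mods <- module_list(net)
  st <- list()
  for (nm in names(mods)) {
    s <- mods[[nm]]$state
    keys <- ls(s)
    if (length(keys)) st[[nm]] <- mget(keys, envir = s)
  }
  st
}

#' Save a network checkpoint
#'
#' Writes the weights, optimizer-independent layer state (normalization
#' running moments) and, as a JSON sidecar `<path>.json`, the full network
#' configuration, so a checkpoint is self-describing.
#'
#' @param net A built network.
#' @param path Destination file path.
#' @export
save_checkpoint <- function(net, path) {
  params <- nn_parameters(net)
  saveRDS(list(weights = lapply(params, function(p) p$v),
               state = collect_state(net)), path)
  cfg <- net$config
  cfg$input_size <- as.integer(cfg$input_size)
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a network checkpoint
#'
#' Rebuilds the network from the JSON sidecar written by [save_checkpoint()]
#' and restores its weights and layer state; the restored network produces
#' bit-identical forward outputs.
#'
#' @param path Checkpoint path as passed to [save_checkpoint()].
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path) || !file.exists(paste0(path, ".json")))
    stop(sprintf("checkpoint '%s' (or its .json sidecar) not found", path),
         call. = FALSE)
  cj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- network_config(variant = cj$variant, input_size = cj$input_size,
                        in_channels = cj$in_channels,
                        base_channels = cj$base_channels,
                        n_stages = cj$n_stages,
                        dilation_rate = cj$dilation_rate,
                        n_heads = cj$n_heads, mlp_ratio = cj$mlp_ratio,
                        token_grid = cj$token_grid,
                        transformer_stages = cj$transformer_stages,
                        norm = cj$norm, upsample_mode = cj$upsample_mode)
  net <- build_network(cfg, seed = 1L)
  blob <- readRDS(path)
  params <- nn_parameters(net)
  stop_if_not(length(params) == length(blob$weights),
              "checkpoint has %d parameter tensors, network expects %d",
              length(blob$weights), length(params))
  for (i in seq_along(params)) params[[i]]$v <- blob$weights[[i]]
  mods <- module_list(net)
  for (nm in names(blob$state))
    for (key in names(blob$state[[nm]]))
      assign(key, blob$state[[nm]][[key]], envir = mods[[nm]]$state)
  net
}
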