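#' Training configuration
#'
#' Defaults follow the published protocol for this architecture family:
#' Adam with `beta1 = 0.9`, `beta2 = 0.999`, an initial learning rate of
#' 1e-4 stepped down to 1e-5 after 400 of 600 epochs, and batch size 6.
#'
#' @param epochs Number of passes over the training slices (default 600).
#' @param lr_initial Learning rate before the switch (default 1e-4).
#' @param lr_after Learning rate from `lr_switch_epoch` on (default 1e-5);
#'   must satisfy `0 < lr_after <= lr_initial`.
#' @param lr_switch_epoch 0-based epoch at which the rate steps down
#'   (default 400).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decays and stabilizer.
#' @param batch_size Slices per optimization step (default 6).
#' @param loss `"dice_bce"` (default), `"dice"` or `"bce"`.
#' @param seed Seed controlling initialization-independent training
#'   randomness (epoch shuffles, per-fold seeds).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 600L, lr_initial = 1e-4, lr_after = 1e-5,
                         lr_switch_epoch = 400L, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8,
                         batch_size = 6L,
                         loss = c("dice_bce", "dice", "bce"), seed = 1L) {
  loss <- match.arg(loss)
  stop_if_not(lr_after > 0 && lr_after <= lr_initial,
              "need 0 < lr_after <= lr_initial")
  stop_if_not(lr_switch_epoch >= 0 && lr_switch_epoch <= epochs,
              "lr_switch_epoch must lie in [0, epochs]")
  stop_if_not(batch_size >= 1, "batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), lr_initial = lr_initial,
                 lr_after = lr_after,
                 lr_switch_epoch = as.integer(lr_switch_epoch),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, batch_size = as.integer(batch_size),
                 loss = loss, seed = as.integer(seed)),
            class = "train_config")
}

#' Stepped learning-rate schedule
#'
#' A right-continuous step function with a single switch: `lr_initial` for
#' epochs before `lr_switch_epoch`, `lr_after` from then on.
#'
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @param cfg A [train_config()].
#' @return The learning rate for that epoch.
#' @examples
#' lr_schedule(0, train_config())    # 1e-4
#' lr_schedule(400, train_config())  # 1e-5
#' @export
lr_schedule <- function(epoch, cfg) {
  stop_if_not(inherits(cfg, "train_config"), "cfg must be a train_config")
  if (epoch < 0 || epoch >= cfg$epochs)
    stop(sprintf("epoch %d outside [0, %d)", epoch, cfg$epochs),
         call. = FALSE)
  if (epoch < cfg$lr_switch_epoch) cfg$lr_initial else cfg$lr_after
}

#' Segmentation loss with analytic logit gradient
#'
#' `dice_bce` is the sum of (1 - soft Dice) and mean binary cross-entropy;
#' both terms are non-negative and vanish only as the prediction approaches
#' the truth.  The soft Dice uses batch-global sums
#' `(2 * sum(p*t) + s) / (sum(p) + sum(t) + s)` with a small smoothing `s`.
#'
#' @param prob Predicted probability array `(H, W, 1, N)`, values in (0, 1).
#' @param truth Matching array (or list of logical masks) with values 0/1.
#' @param type `"dice_bce"`, `"dice"` or `"bce"`.
#' @return List with `loss`, the per-term breakdown, and `dlogits`, the
#'   gradient with respect to the pre-sigmoid logits (what
#'   [nn_backward()] on a network expects).
#' @export
seg_loss <- function(prob, truth, type = c("dice_bce", "dice", "bce")) {
  type <- match.arg(type)
  if (is.list(truth)) {
    t_arr <- array(0, dim(prob))
    for (n in seq_along(truth)) t_arr[, , 1, n] <- truth[[n]] * 1.0
    truth <- t_arr
  }
  if (!all(dim(prob) == dim(truth)))
    stop("prediction and truth shapes differ", call. = FALSE)
  eps <- 1e-7
  p <- pmin(pmax(prob, eps), 1 - eps)
  t <- truth
  n <- length(p)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  dz_bce <- (p - t) / n
  s <- 1e-6
  num <- 2 * sum(p * t) + s
  den <- sum(p) + sum(t) + s
  soft_dice <- num / den
  dterm_dp <- -(2 * t * den - num) / den^2
  dz_dice <- dterm_dp * p * (1 - p)
  out <- switch(type,
                dice_bce = list(loss = (1 - soft_dice) + bce,
                                dlogits = dz_dice + dz_bce),
                dice = list(loss = 1 - soft_dice, dlogits = dz_dice),
                bce = list(loss = bce, dlogits = dz_bce))
  out$soft_dice <- soft_dice
  out$bce <- bce
  out
}

cases_to_batch <- function(cases, idx) {
  H <- nrow(cases[[idx[1]]]$image)
  W <- ncol(cases[[idx[1]]]$image)
  x <- array(0, c(H, W, 1, length(idx)))
  t <- array(0, c(H, W, 1, length(idx)))
  for (j in seq_along(idx)) {
    cs <- cases[[idx[j]]]
    x[, , 1, j] <- cs$image
    g <- if (inherits(cs$mask, "binary_mask")) cs$mask$grid else cs$mask
    t[, , 1, j] <- g * 1.0
  }
  list(x = x, t = t)
}

#' Train a network
#'
#' Full-batch-shuffled mini-batch Adam training with the stepped learning
#' rate of [lr_schedule()].  One epoch is one pass over the training slices;
#' the last partial batch is kept.  Training is deterministic given the
#' configuration seed and initial weights.
#'
#' @param net A built network (modified in place by reference semantics and
#'   also returned).
#' @param cases Nonempty list of cases, each with `image` (`H x W` matrix)
#'   and `mask` (logical matrix or [binary_mask()]).
#' @param cfg A [train_config()].
#' @param checkpoint_path Optional path; when given, a checkpoint is written
#'   after the last epoch.
#' @param log_path Optional path for the per-epoch CSV log.
#' @param verbose Print one line per epoch to standard error?
#' @return List with `net` and `log` (data frame: epoch, lr, loss, seconds).
#' @export
train_network <- function(net, cases, cfg = train_config(),
                          checkpoint_path = NULL, log_path = NULL,
                          verbose = FALSE) {
  stop_if_not(length(cases) >= 1, "training set must be nonempty")
  params <- nn_parameters(net)
  adam_init(params)
  step <- 0L
  log <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    lr <- lr_schedule(epoch - 1L, cfg)
    order <- with_seed(child_seed(cfg$seed, epoch), sample(length(cases)))
    batches <- split(order, ceiling(seq_along(order) / cfg$batch_size))
    losses <- numeric(length(batches))
    for (b in seq_along(batches)) {
      zero_grads(params)
      batch <- cases_to_batch(cases, batches[[b]])
      prob <- nn_forward(net, batch$x, train = TRUE)
      l <- seg_loss(prob, batch$t, cfg$loss)
      if (!is.finite(l$loss))
        stop(sprintf(
          "non-finite loss (%g) at epoch %d batch %d; aborting training",
          l$loss, epoch, b), call. = FALSE)
      nn_backward(net, l$dlogits)
      step <- step + 1L
      adam_step(params, lr, cfg$adam_beta1, cfg$adam_beta2, cfg$adam_eps,
                t = step)
      losses[b] <- l$loss
    }
    secs <- proc.time()[["elapsed"]] - t0
    log[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                               loss = mean(losses), seconds = secs)
    if (verbose)
      message(sprintf("epoch %4d  lr %.1e  loss %.5f  (%.1fs)", epoch, lr,
                      mean(losses), secs))
  }
  log <- do.call(rbind, log)
  if (!is.null(log_path)) write.csv(log, log_path, row.names = FALSE)
  if (!is.null(checkpoint_path)) save_checkpoint(net, checkpoint_path)
  list(net = net, log = log)
}

#' Evaluate a network on a validation fold
#'
#' Binarizes predictions at 0.5 and computes [evaluate_case()] per slice.
#' Cases with undefined metrics are recorded, excluded from the means, and
#' flag the fold.
#'
#' @param net A trained network.
#' @param val_cases List of cases (as in [train_network()], with optional
#'   `patient_id`/`slice_id`).
#' @param fold Fold index recorded in the result (default `NA`).
#' @return A `fold_result`: list with `fold`, `cases` (per-case data frame),
#'   `mean_dsc`, `mean_assd_mm`, `n_undefined` and `flagged`.
#' @export
evaluate_fold <- function(net, val_cases, fold = NA_integer_) {
  rows <- vector("list", length(val_cases))
  for (i in seq_along(val_cases)) {
    cs <- val_cases[[i]]
    truth <- if (inherits(cs$mask, "binary_mask")) cs$mask else
      binary_mask(cs$mask)
    pm <- predict_mask(net, cs$image)
    pred <- binary_mask(pm$masks[[1]], truth$spacing)
    rec <- evaluate_case(pred, truth)
    rows[[i]] <- data.frame(
      patient_id = cs$patient_id %||% NA_character_,
      slice_id = cs$slice_id %||% i,
      dsc = rec$dsc, assd_mm = rec$assd_mm,
      undefined = paste(rec$undefined, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  cases_df <- do.call(rbind, rows)
  n_undef <- sum(cases_df$undefined != "")
  structure(list(fold = fold, cases = cases_df,
                 mean_dsc = mean(cases_df$dsc, na.rm = TRUE),
                 mean_assd_mm = mean(cases_df$assd_mm, na.rm = TRUE),
                 n_undefined = n_undef, flagged = n_undef > 0),
            class = "fold_result")
}

write_fold_csv <- function(fr, path) {
  df <- fr$cases
  summary_row <- data.frame(patient_id = "mean", slice_id = NA,
                            dsc = fr$mean_dsc, assd_mm = fr$mean_assd_mm,
                            undefined = sprintf("%d undefined",
                                                fr$n_undefined),
                            stringsAsFactors = FALSE)
  write.csv(rbind(df, summary_row), path, row.names = FALSE)
}

resolve_cohort <- function(cohort) {
  manifest <- if (is.character(cohort)) read_manifest(cohort) else cohort
  stop_if_not(is.data.frame(manifest), "cohort must be a manifest path or df")
  manifest
}

#' Patient-level k-fold cross-validation of one variant
#'
#' Splits patients into `k` folds (or uses a supplied [kfold_split()]),
#' trains a freshly initialized network per fold on the other `k - 1` folds,
#' evaluates on the held-out fold, and reports per-fold and averaged DSC /
#' ASSD in the fold-1..k-plus-Ave layout.
#'
#' @param variant Architecture variant name (see [make_variant()]).
#' @param cohort Manifest path or manifest data frame
#'   (see [generate_cohort()]).
#' @param k Number of folds.
#' @param cfg A [train_config()].
#' @param net_config Optional [network_config()] template; its `input_size`
#'   must match the cohort images.  Defaults to a config sized from the data.
#' @param folds Optional precomputed fold assignment (used by
#'   [run_ablation()] to keep folds identical across variants).
#' @param out_dir Optional directory for per-fold case CSVs and the summary
#'   CSV.
#' @return A `cv_result`: list with `variant`, `fold_results`, `folds`, and
#'   `summary` (data frame with columns `metric`, `fold_1`..`fold_k`, `Ave`).
#' @export
cross_validate <- function(variant, cohort, k, cfg = train_config(),
                           net_config = NULL, folds = NULL, out_dir = NULL) {
  manifest <- resolve_cohort(cohort)
  cases <- load_cases(manifest)
  patients <- unique(manifest$patient_id)
  if (is.null(folds)) folds <- kfold_split(patients, k, cfg$seed)
  stop_if_not(folds$k == k, "fold assignment has k = %d, expected %d",
              folds$k, k)
  H <- nrow(cases[[1]]$image)
  W <- ncol(cases[[1]]$image)
  if (is.null(net_config))
    net_config <- network_config(variant = variant, input_size = c(H, W),
                                 base_channels = 8L)
  net_config$variant <- variant
  pid <- vapply(cases, function(cs) cs$patient_id, character(1))
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fold_results <- vector("list", k)
  for (f in seq_len(k) - 1L) {
    train_cases <- cases[pid %in% fold_complement(folds, f)]
    val_cases <- cases[pid %in% fold_patients(folds, f)]
    net <- build_network(net_config, seed = child_seed(cfg$seed, 1000L + f))
    fit <- train_network(net, train_cases, cfg)
    fr <- evaluate_fold(fit$net, val_cases, fold = f)
    fold_results[[f + 1L]] <- fr
    if (!is.null(out_dir))
      write_fold_csv(fr, file.path(out_dir,
                                   sprintf("%s_fold%d_cases.csv", variant,
                                           f + 1L)))
  }
  dscs <- vapply(fold_results, function(fr) fr$mean_dsc, numeric(1))
  assds <- vapply(fold_results, function(fr) fr$mean_assd_mm, numeric(1))
  summary <- data.frame(metric = c("DSC", "ASSD_mm"),
                        rbind(dscs, assds), row.names = NULL)
  names(summary)[-1] <- paste0("fold_", seq_len(k))
  summary$Ave <- c(mean(dscs), mean(assds))
  if (!is.null(out_dir))
    write.csv(summary, file.path(out_dir, sprintf("%s_summary.csv", variant)),
              row.names = FALSE)
  structure(list(variant = variant, fold_results = fold_results,
                 folds = folds, summary = summary),
            class = "cv_result")
}

#' Ablation study across the four architecture variants
#'
#' Runs [cross_validate()] for `unet`, `unet_dr`, `unet_rt` and `dctr` under
#' identical fold assignments and identical per-fold initialization seeds, so
#' the only difference between rows is the per-stage block type.
#'
#' @inheritParams cross_validate
#' @param variants Variant names to compare (default all four).
#' @return An `ablation_report`: list with `results` (per variant), `folds`,
#'   and `table`, a data frame with one row per variant and columns
#'   `variant`, `dsc_fold_1..k`, `dsc_ave`, `assd_fold_1..k`, `assd_ave`.
#' @export
run_ablation <- function(cohort, k, cfg = train_config(), net_config = NULL,
                         variants = VARIANTS, out_dir = NULL) {
  manifest <- resolve_cohort(cohort)
  folds <- kfold_split(unique(manifest$patient_id), k, cfg$seed)
  results <- list()
  for (v in variants)
    results[[v]] <- cross_validate(v, manifest, k, cfg,
                                   net_config = net_config, folds = folds,
                                   out_dir = out_dir)
  tab <- do.call(rbind, lapply(variants, function(v) {
    s <- results[[v]]$summary
    dsc <- unlist(s[s$metric == "DSC", -1])
    assd <- unlist(s[s$metric == "ASSD_mm", -1])
    df <- data.frame(variant = v, t(dsc), t(assd))
    names(df) <- c("variant", paste0("dsc_", names(dsc)),
                   paste0("assd_", names(assd)))
    df
  }))
  names(tab) <- sub("_Ave$", "_ave", names(tab))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out_dir, "ablation_summary.csv"),
              row.names = FALSE)
  }
  structure(list(results = results, folds = folds, table = tab),
            class = "ablation_report")
}
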