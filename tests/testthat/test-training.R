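test_that("learning-rate schedule steps once at the switch epoch", {
  cfg <- train_config()
  expect_identical(lr_schedule(0, cfg), 1e-4)
  expect_identical(lr_schedule(399, cfg), 1e-4)
  expect_identical(lr_schedule(400, cfg), 1e-5)
  expect_identical(lr_schedule(599, cfg), 1e-5)
  lrs <- vapply(0:599, lr_schedule, numeric(1), cfg = cfg)
  expect_identical(sum(diff(lrs) != 0), 1L)       # exactly one switch
  expect_true(all(lrs %in% c(1e-4, 1e-5)))
  expect_error(lr_schedule(-1, cfg), "outside")
  expect_error(lr_schedule(600, cfg), "outside")
  expect_error(train_config(lr_initial = 1e-5, lr_after = 1e-4),
               "lr_after")
})

test_that("dice+bce loss behaves at its extremes", {
  set.seed(1)
  t <- array(0, c(16, 16, 1, 1))
  t[5:10, 5:10, 1, 1] <- 1
  eps <- 1e-6
  near_t <- pmin(pmax(t, eps), 1 - eps)
  expect_lt(seg_loss(near_t, t)$loss, 0.01)
  inverted <- pmin(pmax(1 - t, eps), 1 - eps)
  expect_gt(seg_loss(inverted, t)$loss, seg_loss(near_t, t)$loss * 100)
  expect_gt(seg_loss(inverted, t)$loss, 1.9)      # both terms near maximal
  expect_error(seg_loss(array(0.5, c(4, 4, 1, 1)), t), "shapes differ")
})

test_that("the soft-Dice term approximates the hard Dice for crisp preds", {
  set.seed(2)
  truth <- random_mask(16, 16)
  t <- array(truth * 1.0, c(16, 16, 1, 1))
  noisy <- pmin(pmax(t * 0.97 + 0.015 + rnorm(length(t), 0, 0.005),
                     1e-6), 1 - 1e-6)
  hard <- dice(bm(matrix(noisy[, , 1, 1] > 0.5, 16, 16)), bm(truth))
  expect_lt(abs((1 - seg_loss(noisy, t, "dice")$loss) - hard), 0.05)
})

test_that("loss gradient w.r.t. logits matches finite differences", {
  set.seed(3)
  z <- array(rnorm(6 * 6), c(6, 6, 1, 1))
  t <- array((matrix(rnorm(36), 6) > 0) * 1.0, c(6, 6, 1, 1))
  p <- 1 / (1 + exp(-z))
  g <- seg_loss(p, t)$dlogits
  ng <- numeric_input_grad(function(zz)
    seg_loss(1 / (1 + exp(-zz)), t)$loss, z, 1, seq_along(z))
  expect_equal(as.numeric(g), ng, tolerance = 1e-6)
})

test_that("training reduces the loss and is seed-deterministic", {
  cases <- overfit_cases(size = 32L, n = 2L)
  net1 <- build_network(tiny_net_config(), seed = 5)
  fit1 <- train_network(net1, cases, tiny_train_config(epochs = 12L))
  expect_lt(fit1$log$loss[12], fit1$log$loss[1])
  expect_identical(nrow(fit1$log), 12L)
  expect_true(all(fit1$log$lr == 1e-3))
  net2 <- build_network(tiny_net_config(), seed = 5)
  fit2 <- train_network(net2, cases, tiny_train_config(epochs = 12L))
  expect_identical(fit1$log$loss, fit2$log$loss)
  expect_error(train_network(net1, list(), tiny_train_config()), "nonempty")
})

test_that("fold evaluation aggregates defined cases and flags empties", {
  # the oracle predictors dispatch through the package's forward generic
  .S3method("nn_forward", "threshold_oracle",
            function(mod, x, train = FALSE)
              array((x > 0.5) * 0.98 + 0.01, c(dim(x)[1], dim(x)[2], 1, 1)))
  .S3method("nn_forward", "background_oracle",
            function(mod, x, train = FALSE)
              array(0.01, c(dim(x)[1], dim(x)[2], 1, 1)))
  spec <- phantom_spec(image_size = 32, lesion_boundary_roughness = 0,
                      noise_sigma = 0, bias_field_amplitude = 0,
                      lesion_contrast = 5)
  cases <- lapply(1:3, function(i) {
    ph <- generate_phantom(spec, seed = 40 + i)
    list(image = ph$image, mask = ph$mask, patient_id = sprintf("p%d", i),
         slice_id = 1L)
  })
  perfect <- structure(list(), class = "threshold_oracle")
  fr <- evaluate_fold(perfect, cases, fold = 0L)
  expect_identical(fr$mean_dsc, 1)
  expect_identical(fr$mean_assd_mm, 0)
  expect_false(fr$flagged)
  expect_identical(fr$mean_dsc, mean(fr$cases$dsc))      # hand-averaged
  empty <- structure(list(), class = "background_oracle")
  fr2 <- evaluate_fold(empty, cases, fold = 0L)
  expect_identical(fr2$n_undefined, 3L)
  expect_true(fr2$flagged)
  expect_true(all(fr2$cases$dsc == 0))
  expect_true(all(is.na(fr2$cases$assd_mm)))
})

test_that("cross-validation validates every patient exactly once", {
  d <- file.path(tempdir(), "cvcoh")
  unlink(d, recursive = TRUE)
  mf <- generate_cohort(6, phantom_spec(image_size = 32,
                                        slices_per_patient = 2, seed = 3), d)
  out <- file.path(tempdir(), "cvout")
  unlink(out, recursive = TRUE)
  cv <- cross_validate("unet", mf, 3, tiny_train_config(epochs = 1L),
                       net_config = tiny_net_config("unet"), out_dir = out)
  expect_length(cv$fold_results, 3)
  seen <- unlist(lapply(cv$fold_results, function(fr)
    unique(fr$cases$patient_id)))
  expect_setequal(seen, unique(read_manifest(mf)$patient_id))
  expect_identical(anyDuplicated(seen), 0L)
  # the Ave column is the mean of the fold columns
  s <- cv$summary
  expect_equal(s$Ave, rowMeans(s[, paste0("fold_", 1:3)]))
  # the summary CSV parses back to the same numbers
  s2 <- read.csv(file.path(out, "unet_summary.csv"))
  expect_equal(s2$Ave, s$Ave)
  expect_true(all(file.exists(file.path(out, sprintf(
    "unet_fold%d_cases.csv", 1:3)))))
})
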