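test_that("ce_loss matches its closed forms", {
  target <- list(matrix(c(1L, 0L, 0L, 1L), 2, 2), matrix(0L, 2, 2))
  uninformative <- array(0.5, c(2, 2, 2))
  expect_equal(ce_loss(uninformative, target), log(2), tolerance = 1e-12)
  # single pixel, r = 1, p = 0.25
  expect_equal(ce_loss(array(0.25, c(1, 1, 2)),
                       list(matrix(1L), matrix(1L))),
               -log(0.25), tolerance = 1e-12)
  tarr <- array(c(target[[1]], target[[2]]), c(2, 2, 2))
  perfect <- pmin(pmax(tarr, 1e-9), 1 - 1e-9)
  expect_lt(ce_loss(perfect, target), 1e-6)
  expect_error(ce_loss(array(0.5, c(4, 4, 2)), target), "shape")
})

test_that("seg_metrics computes the count arithmetic of the metric suite", {
  truth <- matrix(0L, 20, 20); truth[1:10, 1:10] <- 1L           # 100 px
  pred <- matrix(0L, 20, 20); pred[5:10, 1:10] <- 1L; pred[11:12, 1:10] <- 1L
  m <- seg_metrics(pred, truth)                                   # 80 px, 60 overlap
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.60)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
  expect_equal(m$iou, 0.5)
  same <- seg_metrics(truth, truth)
  expect_equal(unlist(same[c("precision", "recall", "f1", "iou")]),
               c(precision = 1, recall = 1, f1 = 1, iou = 1))
  disjoint <- matrix(0L, 20, 20); disjoint[15:18, 15:18] <- 1L
  md <- seg_metrics(disjoint, truth)
  expect_equal(unlist(md[c("precision", "recall", "f1", "iou")]),
               c(precision = 0, recall = 0, f1 = 0, iou = 0))
  expect_error(seg_metrics(pred, matrix(0L, 5, 5)), "dimensions")
})

test_that("seg_metrics symmetry and the Dice-Jaccard identity hold", {
  set.seed(7)
  for (i in 1:20) {
    a <- matrix(rbinom(400, 1, 0.3), 20, 20)
    b <- matrix(rbinom(400, 1, 0.4), 20, 20)
    m1 <- seg_metrics(a, b); m2 <- seg_metrics(b, a)
    expect_equal(m1$precision, m2$recall)
    expect_equal(m1$recall, m2$precision)
    expect_equal(m1$f1, m2$f1)
    expect_equal(m1$iou, m2$iou)
    if (m1$f1 > 0) expect_equal(m1$iou, m1$f1 / (2 - m1$f1), tolerance = 1e-12)
  }
})

test_that("seg_metrics empty-denominator conventions keep degenerate cases sane", {
  e <- matrix(0L, 8, 8); f <- matrix(0L, 8, 8); f[3, 3] <- 1L
  both <- seg_metrics(e, e)
  expect_equal(unlist(both[c("precision", "recall", "f1", "iou")]),
               c(precision = 1, recall = 1, f1 = 1, iou = 1))
  expect_equal(seg_metrics(e, f)$precision, 0)
  expect_equal(seg_metrics(f, e)$recall, 0)
})

test_that("the plain U-Net has the reference layer census", {
  cnt <- model_layer_counts(build_model(seg_model_config("unet", base_width = 2)))
  expect_equal(cnt$conv3, 19)
  expect_equal(cnt$maxpool, 4)
  expect_equal(cnt$upsample, 4)
  expect_equal(cnt$conv1, 1)
})

test_that("unet3p carries strictly more skip connections than unet at equal depth", {
  skips <- vapply(c("unet", "unetpp", "unet3p"), function(a)
    model_layer_counts(build_model(seg_model_config(a, base_width = 2)))$skips, 0L)
  expect_gt(skips[["unet3p"]], skips[["unet"]])
  expect_gt(skips[["unetpp"]], skips[["unet"]])
  expect_error(seg_model_config("resnet"))
})

test_that("every architecture maps HxWx3 input to HxWx2 probabilities in (0,1)", {
  X <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  for (arch in c("unet", "unetpp", "unet3p")) {
    m <- build_model(seg_model_config(arch, base_width = 2, input_size = 32),
                     init_seed = 2)
    p <- oktopo:::predict_probs(m, X)
    expect_equal(dim(p), c(32, 32, 2, 1))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("batched convolution kernels agree with per-sample evaluation", {
  # batch sizes chosen to force a partial final processing chunk; tolerances
  # reflect the kernels computing in single precision
  set.seed(9)
  x <- array(rnorm(64 * 64 * 8 * 3), c(64, 64, 8, 3))
  w <- array(rnorm(3 * 3 * 8 * 4, sd = 0.1), c(3, 3, 8, 4))
  b <- rnorm(4)
  full <- oktopo:::cpp_conv_fwd(x, w, b)
  for (n in 1:3)
    expect_equal(full[, , , n],
                 oktopo:::cpp_conv_fwd(x[, , , n, drop = FALSE], w, b)[, , , 1],
                 tolerance = 1e-5)
  dout <- array(rnorm(64 * 64 * 4 * 3), c(64, 64, 4, 3))
  bw <- oktopo:::cpp_conv_bwd(x, w, dout)
  dws <- array(0, dim(w))
  for (n in 1:3) {
    o <- oktopo:::cpp_conv_bwd(x[, , , n, drop = FALSE], w,
                               dout[, , , n, drop = FALSE])
    dws <- dws + o$dw
    expect_equal(bw$dx[, , , n], o$dx[, , , 1], tolerance = 1e-5)
  }
  expect_equal(bw$dw, dws, tolerance = 1e-5)
})

test_that("backpropagated gradients match numerical differentiation", {
  set.seed(40)
  X <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  Y <- array(rbinom(16 * 16 * 2 * 2, 1, 0.3), c(16, 16, 2, 2))
  for (arch in c("unet", "unetpp", "unet3p")) {
    m <- build_model(seg_model_config(arch, base_width = 2, input_size = 32),
                     init_seed = 6)
    # random biases keep ReLU pre-activations away from the kink at 0
    for (nm in grep("\\.b$", names(m$params), value = TRUE))
      m$params[[nm]] <- rnorm(length(m$params[[nm]]), sd = 0.1)
    lg <- oktopo:::model_loss_grads(m, X, Y)
    # the step and tolerance account for the kernels running in single
    # precision: smaller steps drown in float noise
    h <- 1e-3
    head_w <- if (arch == "unetpp") "h4.w" else "out.w"
    for (nm in c("e1a.w", "e2b.w", head_w, "e3a.b")) {
      for (idx in c(1L, 2L)) {
        m2 <- m
        m2$params[[nm]][idx] <- m$params[[nm]][idx] + h
        l1 <- oktopo:::model_loss_grads(m2, X, Y)$loss
        m2$params[[nm]][idx] <- m$params[[nm]][idx] - h
        l0 <- oktopo:::model_loss_grads(m2, X, Y)$loss
        num <- (l1 - l0) / (2 * h)
        err <- abs(lg$grads[[nm]][idx] - num) / max(5e-4, abs(num))
        expect_lt(err, 0.05)
      }
    }
  }
})

test_that("augment is seeded, identity at null settings, and area-preserving", {
  cs <- tiny_dataset(1, seed = 14)[[1]]
  img <- unclass(cs$image)
  masks <- list(unclass(cs$pupil_mask), unclass(cs$tz_mask))
  a1 <- augment(img, masks, seed = 5)
  a2 <- augment(img, masks, seed = 5)
  expect_identical(a1, a2)
  a3 <- augment(img, masks, seed = 6)
  expect_false(identical(a1$image, a3$image))
  idty <- augment(img, masks, seed = 5, rot_range = 0, crop_min_area = 1,
                  noise_sd = 0)
  expect_identical(idty$image, img)
  expect_equal(idty$masks[[1]], masks[[1]], ignore_attr = TRUE)
  for (s in 1:5) {
    a <- augment(img, masks, seed = s)
    expect_lt(abs(sum(a$masks[[1]]) - sum(masks[[1]])) / sum(masks[[1]]), 0.3)
  }
})

# One small training run shared by the convergence and prediction tests.
fit_ds <- tiny_dataset(48, seed = 2)
fit_cfg <- seg_model_config("unet", base_width = 8, input_size = 32)
fit_tc <- train_config(learning_rate = 6e-3, batch_size = 8, epochs = 45,
                       input_size_px = 32, seed = 1)
fit <- train(fit_ds, build_model(fit_cfg), fit_tc)

test_that("training on easy cases cuts the loss by an order of magnitude", {
  expect_length(fit$history, 45)
  expect_lt(fit$history[45], fit$history[1] / 10)
  expect_setequal(c(fit$train_idx, fit$test_idx), seq_along(fit_ds))
})

test_that("training is seeded end to end and validates its inputs", {
  cfg <- seg_model_config("unet", base_width = 2, input_size = 32)
  tc <- train_config(learning_rate = 3e-3, batch_size = 8, epochs = 3,
                     input_size_px = 32, seed = 4)
  r1 <- train(fit_ds, build_model(cfg), tc)
  r2 <- train(fit_ds, build_model(cfg), tc)
  expect_equal(r1$history, r2$history, tolerance = 1e-12)
  expect_equal(r1$model$params, r2$model$params, tolerance = 1e-12)
  expect_error(train(list(), build_model(cfg), tc), "empty")
  expect_error(train(fit_ds, build_model(cfg),
                     train_config(batch_size = 100, input_size_px = 32)),
               "batch_size")
  expect_error(train_config(batch_size = 0))
})

test_that("predict_masks honours thresholds and native resolution", {
  ds <- fit_ds
  tr <- fit
  held <- ds[tr$test_idx]
  ious <- vapply(held, function(cs) {
    pm <- predict_masks(tr$model, cs$image)
    seg_metrics(pm$pupil, cs$pupil_mask)$iou
  }, 0)
  expect_gt(mean(ious), 0.8)
  cs <- held[[1]]
  pm <- predict_masks(tr$model, cs$image)
  expect_equal(dim(unclass(pm$pupil)), dim(unclass(cs$pupil_mask)))
  empty <- predict_masks(tr$model, cs$image, threshold = 1.0)
  expect_equal(sum(unclass(empty$pupil)) + sum(unclass(empty$tz)), 0)
  nn <- predict_masks(tr$model, cs$image, mask_resize = "nearest")
  expect_equal(dim(unclass(nn$pupil)), dim(unclass(cs$pupil_mask)))
})

test_that("checkpoints round-trip the model and its configuration", {
  m <- build_model(seg_model_config("unetpp", base_width = 2, input_size = 32),
                   init_seed = 11)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$config, m$config)
  expect_equal(m2$params, m$params)
  X <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_equal(oktopo:::predict_probs(m2, X), oktopo:::predict_probs(m, X))
})
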