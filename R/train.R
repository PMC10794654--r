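#' Training configuration
#'
#' Defaults reproduce the reference training strategy: Adam with initial
#' learning rate 1e-4, batch size 32, 224x224 inputs, 100 epochs. Reduced
#' settings (smaller batches, 64 px inputs, fewer epochs) are appropriate for
#' CPU-scale experiments on synthetic data.
#'
#' @param learning_rate initial Adam step size.
#' @param lr_schedule `"constant"` (default) keeps the step size fixed;
#'   `"cosine"` anneals it to near zero over the run (at short epoch budgets
#'   the annealed run takes fewer effective steps and converges less far, so
#'   constant is the default).
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param input_size_px square network input side (divisible by 16).
#' @param seed integer seed driving weight init, the train/test split and
#'   shuffling.
#' @param optimizer only `"adam"` is supported.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L, epochs = 100L,
                         input_size_px = 224L, seed = 0L, optimizer = "adam",
                         lr_schedule = c("constant", "cosine")) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            input_size_px %% 16 == 0, identical(optimizer, "adam"))
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), input_size_px = as.integer(input_size_px),
                 seed = as.integer(seed), optimizer = optimizer,
                 lr_schedule = lr_schedule),
            class = "train_config")
}

modify_train_config <- function(tc, ...) {
  up <- list(...)
  for (n in names(up)) tc[[n]] <- up[[n]]
  do.call(train_config, unclass(tc))
}

# Stack cases into network tensors at the training resolution.
cases_to_tensors <- function(cases, size) {
  n <- length(cases)
  X <- array(0, c(size, size, 3L, n))
  Y <- array(0, c(size, size, 2L, n))
  for (i in seq_len(n)) {
    cs <- cases[[i]]
    X[, , , i] <- resize_bilinear(unclass(cs$image), size, size)
    Y[, , 1L, i] <- resize_mask(cs$pupil_mask, size, size)
    Y[, , 2L, i] <- resize_mask(cs$tz_mask, size, size)
  }
  list(X = X, Y = Y)
}

he_init_params <- function(params) {
  for (n in names(params)) {
    p <- params[[n]]
    params[[n]] <- init_param(n, if (is.null(dim(p))) length(p) else dim(p))
  }
  params
}

#' Train a segmentation model
#'
#' Optimises the mean binary cross-entropy (with deep-supervision heads
#' averaged at equal weight, where the architecture has them) with Adam. The
#' dataset is split into training and held-out test subsets (80/20 by
#' default); weight initialisation, the split and per-epoch shuffling are all
#' driven by `tc$seed`, so a run is reproducible end to end.
#'
#' @param dataset non-empty list of cases with `image`, `pupil_mask`,
#'   `tz_mask` (e.g. from [generate_dataset()]).
#' @param model a `seg_model` from [build_model()]; its parameters are
#'   re-initialised from `tc$seed` unless `reinit = FALSE` (the checkpoint
#'   fine-tuning hook).
#' @param tc a [train_config()].
#' @param val_fraction held-out fraction (0 trains on everything, as used by
#'   [kfold_evaluate()]).
#' @param reinit re-initialise weights from `tc$seed`.
#' @param verbose print per-epoch losses.
#' @param snapshot_every if set, keep a copy of the parameters every this
#'   many epochs (in `$snapshots`, keyed by epoch) for learning-curve
#'   inspection.
#' @param tail_average if > 0, the returned model's weights are the average
#'   of the parameter values after each of the final `tail_average` epochs
#'   (stochastic weight averaging), which damps the epoch-to-epoch
#'   oscillation of constant-rate Adam around the optimum.
#' @return list with `model` (trained), `history` (per-epoch mean training
#'   loss), `train_idx`, `test_idx`, `snapshots`.
#' @export
train <- function(dataset, model, tc, val_fraction = 0.2, reinit = TRUE,
                  verbose = FALSE, snapshot_every = NULL, tail_average = 0L) {
  if (length(dataset) == 0L) stop("empty dataset")
  if (tc$batch_size > length(dataset)) stop("batch_size exceeds the dataset size")
  withr::with_seed(tc$seed, {
    if (reinit) model$params <- he_init_params(model$params)
    n <- length(dataset)
    test_idx <- if (val_fraction > 0)
      sort(sample.int(n, size = max(1L, round(val_fraction * n)))) else integer(0)
    train_idx <- setdiff(seq_len(n), test_idx)
    if (tc$batch_size > length(train_idx))
      stop("batch_size exceeds the training split size")
    tens <- cases_to_tensors(dataset[train_idx], tc$input_size_px)
    m <- lapply(model$params, function(p) p * 0)
    v <- m
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    swa <- NULL
    swa_n <- 0L
    snapshots <- list()
    history <- numeric(tc$epochs)
    nt <- length(train_idx)
    for (ep in seq_len(tc$epochs)) {
      lr_ep <- if (identical(tc$lr_schedule, "cosine"))
        tc$learning_rate * 0.5 * (1 + cos(pi * (ep - 1) / tc$epochs))
      else tc$learning_rate
      ord <- sample.int(nt)
      starts <- seq(1L, nt - tc$batch_size + 1L, by = tc$batch_size)
      ep_loss <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        sel <- ord[starts[bi]:(starts[bi] + tc$batch_size - 1L)]
        lg <- model_loss_grads(model,
                               tens$X[, , , sel, drop = FALSE],
                               tens$Y[, , , sel, drop = FALSE])
        step <- step + 1L
        for (nm in names(model$params)) {
          gr <- lg$grads[[nm]]
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gr
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gr * gr
          mh <- m[[nm]] / (1 - b1^step)
          vh <- v[[nm]] / (1 - b2^step)
          model$params[[nm]] <- model$params[[nm]] - lr_ep * mh / (sqrt(vh) + eps)
        }
        ep_loss[bi] <- lg$loss
      }
      history[ep] <- mean(ep_loss)
      if (tail_average > 0L && ep > tc$epochs - tail_average) {
        swa_n <- swa_n + 1L
        if (is.null(swa)) swa <- model$params
        else for (nm in names(swa)) swa[[nm]] <- swa[[nm]] + model$params[[nm]]
      }
      if (!is.null(snapshot_every) && ep %% snapshot_every == 0L)
        snapshots[[as.character(ep)]] <- model$params
      if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, history[ep]))
    }
    if (swa_n > 0L)
      model$params <- lapply(swa, function(p) p / swa_n)
    list(model = model, history = history,
         train_idx = train_idx, test_idx = test_idx,
         snapshots = snapshots)
  })
}

#' Segment an image with a trained model
#'
#' The image is resized to the network input size; by default the per-channel
#' probabilities are resized back to the native resolution bilinearly and then
#' thresholded, so downstream px-to-mm geometry runs at the native scale
#' (e.g. 50 px/mm) with a smooth decision boundary. `mask_resize = "nearest"`
#' instead thresholds on the network grid and upsamples the binary masks by
#' nearest neighbour.
#'
#' @param model trained `seg_model`.
#' @param image `topography_image` or (H, W, 3) array in \[0, 1\].
#' @param threshold probability cut-off (default 0.5); a threshold of 1 yields
#'   empty masks, which propagate as such.
#' @param mask_resize `"bilinear"` (probabilities, then threshold) or
#'   `"nearest"` (binary masks).
#' @param tta average the probabilities over the four axis flips of the
#'   input (test-time augmentation); slower but slightly more precise.
#' @return list of `region_mask`s `pupil` and `tz` at the image's native
#'   resolution.
#' @export
predict_masks <- function(model, image, threshold = 0.5,
                          mask_resize = c("bilinear", "nearest"),
                          tta = FALSE) {
  mask_resize <- match.arg(mask_resize)
  img <- unclass(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  s <- model$config$input_size
  X <- array(resize_bilinear(img, s, s), c(s, s, 3L, 1L))
  probs <- if (tta) {
    flips <- list(
      identity,
      function(a) a[rev(seq_len(dim(a)[1])), , , , drop = FALSE],
      function(a) a[, rev(seq_len(dim(a)[2])), , , drop = FALSE],
      function(a) a[rev(seq_len(dim(a)[1])), rev(seq_len(dim(a)[2])), , ,
                    drop = FALSE])
    acc <- 0
    for (f in flips) acc <- acc + f(predict_probs(model, f(X)))
    (acc / length(flips))[, , , 1L]
  } else {
    predict_probs(model, X)[, , , 1L]
  }
  one <- function(ch) {
    if (mask_resize == "bilinear") {
      matrix(as.integer(resize_bilinear(probs[, , ch], H, W) >= threshold), H, W)
    } else {
      resize_mask(matrix(as.integer(probs[, , ch] >= threshold), s, s), H, W)
    }
  }
  list(pupil = region_mask(one(1L), "pupil"),
       tz = region_mask(one(2L), "treatment_zone"))
}

#' Augment an image/mask pair
#'
#' Seeded random rotation, crop-and-resize and additive Gaussian pixel noise
#' (noise on the image only); the identical geometric transform is applied to
#' the masks. With `rot_range = 0`, `crop_min_area = 1` and `noise_sd = 0`
#' the input is returned unchanged.
#'
#' @param image (H, W, 3) array in \[0, 1\].
#' @param masks list of binary masks (same H, W).
#' @param seed integer seed.
#' @param rot_range maximal absolute rotation in degrees.
#' @param crop_min_area minimal retained area fraction of the random crop.
#' @param noise_sd standard deviation of the additive image noise.
#' @return list `image`, `masks` with the original dimensions.
#' @export
augment <- function(image, masks, seed, rot_range = 15, crop_min_area = 0.85,
                    noise_sd = 0.02) {
  img <- unclass(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  withr::with_seed(as.integer(seed), {
    angle <- if (rot_range > 0) stats::runif(1, -rot_range, rot_range) else 0
    frac <- if (crop_min_area < 1) sqrt(stats::runif(1, crop_min_area, 1)) else 1
    ch <- max(1L, round(frac * H)); cw <- max(1L, round(frac * W))
    oy <- if (H > ch) sample.int(H - ch + 1L, 1L) else 1L
    ox <- if (W > cw) sample.int(W - cw + 1L, 1L) else 1L
    geom_img <- function(x, mask = FALSE) {
      if (angle != 0) {
        x <- as.array(EBImage::rotate(x, angle, filter = if (mask) "none" else "bilinear",
                                      output.dim = c(H, W), bg.col = 0))
      }
      if (ch < H || cw < W) {
        x <- if (length(dim(x)) == 3L) x[oy:(oy + ch - 1L), ox:(ox + cw - 1L), , drop = FALSE]
             else x[oy:(oy + ch - 1L), ox:(ox + cw - 1L), drop = FALSE]
        x <- if (mask) resize_nearest(x, H, W) else resize_bilinear(x, H, W)
      }
      x
    }
    out_img <- geom_img(img)
    if (noise_sd > 0)
      out_img <- pmin(pmax(out_img + stats::rnorm(length(out_img), sd = noise_sd), 0), 1)
    out_masks <- lapply(masks, function(m) {
      mm <- geom_img(as_binary_matrix(m) * 1.0, mask = TRUE)
      matrix(as.integer(mm > 0.5), H, W)
    })
    list(image = out_img, masks = out_masks)
  })
}
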