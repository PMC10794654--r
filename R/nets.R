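#' Segmentation model configuration
#'
#' Describes one of the three supported encoder-decoder architectures used to
#' segment the pupil and the treatment zone as a two-channel multi-label
#' problem (the regions may overlap, so each output channel gets its own
#' sigmoid rather than sharing a softmax).
#'
#' All three share a 4-stage encoder (5 resolution levels) whose channel
#' widths double per stage starting at `base_width`:
#' \itemize{
#'   \item `unet`: plain long skip connections; 19 3x3 convolution layers,
#'     4 max-pooling layers, 4 upsampling layers and one final 1x1 convolution.
#'   \item `unetpp`: nested dense skip connections with deep supervision
#'     (U-Net++).
#'   \item `unet3p`: full-scale skip connections joining every encoder and
#'     decoder level, with deep-supervision side heads (U-Net3+). The
#'     classification-guided module is gated behind `cls_guided` and off by
#'     default.
#' }
#'
#' @param arch one of `"unet"`, `"unetpp"`, `"unet3p"`.
#' @param base_width channels of the first encoder stage (64 at paper scale;
#'   8 is a practical reduced width for CPU-scale experiments).
#' @param input_size square input side in px; must be divisible by 16.
#' @param in_channels input image channels (3 for RGB topography exports).
#' @param out_channels output region channels (pupil, treatment zone).
#' @param deep_supervision average auxiliary head losses into the objective
#'   (only meaningful for `unetpp`/`unet3p`).
#' @param norm `"none"` (default) gives plain conv + ReLU blocks, which at
#'   the reference learning rate converged further per epoch on this imagery
#'   than normalised blocks; `"instance"` inserts instance normalisation
#'   between every hidden convolution and its ReLU.
#' @param cls_guided reserved flag for the U-Net3+ classification-guided
#'   module; must remain `FALSE` (not implemented).
#' @return a `seg_model_config` list.
#' @export
seg_model_config <- function(arch = c("unet", "unetpp", "unet3p"),
                             base_width = 64L, input_size = 224L,
                             in_channels = 3L, out_channels = 2L,
                             deep_supervision = NULL, norm = c("none", "instance"),
                             cls_guided = FALSE) {
  arch <- match.arg(arch)
  norm <- match.arg(norm)
  stopifnot(base_width >= 1, input_size >= 32, input_size %% 16 == 0,
            in_channels >= 1, out_channels >= 1)
  if (isTRUE(cls_guided)) stop("the classification-guided module is not implemented")
  if (is.null(deep_supervision)) deep_supervision <- arch != "unet"
  structure(list(arch = arch, base_width = as.integer(base_width),
                 depth = 4L, input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 deep_supervision = isTRUE(deep_supervision), norm = norm),
            class = "seg_model_config")
}

# Parameter context: P(name, shape) returns the graph node id of a parameter,
# creating and He-initialising it on first use (only during build_model's
# tracing pass). `shape` is c(k, k, cin, cout) for weights or a scalar length
# for biases.
make_param_ctx <- function(g, store, allow_create) {
  ids <- new.env(parent = emptyenv())
  P <- function(name, shape) {
    if (!is.null(ids[[name]])) return(ids[[name]])
    if (is.null(store$params[[name]])) {
      if (!allow_create) stop("unknown parameter: ", name)
      store$params[[name]] <- init_param(name, shape)
    } else if (length(shape) > 1L &&
               !identical(dim(store$params[[name]]), as.integer(shape))) {
      stop("parameter shape mismatch for ", name)
    }
    id <- ag_input(g, store$params[[name]])
    ids[[name]] <- id
    id
  }
  attr(P, "ids") <- ids
  P
}

# Parameter initialisation by naming convention: .w He-normal, .g (norm
# gain) ones, every other vector (biases, norm shifts) zeros.
init_param <- function(name, shape) {
  if (length(shape) > 1L)
    return(array(stats::rnorm(prod(shape), sd = sqrt(2 / prod(shape[1:3]))), shape))
  if (grepl("\\.g$", name)) rep(1, shape) else numeric(shape)
}

# Hidden blocks are conv [-> instance norm] -> ReLU; head convolutions
# (relu = FALSE) are plain conv + bias. `g$use_norm` is set per forward pass
# from the model configuration.
cv <- function(g, x, P, name, cout, k = 3L, relu = TRUE) {
  cin <- dim(ag_value(g, x))[3]
  w <- P(paste0(name, ".w"), c(k, k, cin, cout))
  b <- P(paste0(name, ".b"), cout)
  y <- ag_conv(g, x, w, b)
  if (!relu) return(y)
  if (isTRUE(g$use_norm))
    y <- ag_instnorm(g, y, P(paste0(name, ".g"), cout), P(paste0(name, ".s"), cout))
  ag_relu(g, y)
}

dconv <- function(g, x, P, name, cout) {
  cv(g, cv(g, x, P, paste0(name, "a"), cout), P, paste0(name, "b"), cout)
}

fw_encoder <- function(g, x, P, w) {
  e <- vector("list", 5L)
  cur <- x
  for (i in 1:5) {
    if (i > 1) cur <- ag_maxpool(g, cur, 2L)
    cur <- dconv(g, cur, P, sprintf("e%d", i), w * 2L^(i - 1L))
    e[[i]] <- cur
  }
  e
}

fw_unet <- function(g, x, P, cfg) {
  w <- cfg$base_width
  e <- fw_encoder(g, x, P, w)
  d <- e[[5]]
  for (j in 4:1) {
    d <- ag_concat(g, list(ag_upsample(g, d, 2L), e[[j]]))
    d <- dconv(g, d, P, sprintf("d%d", j), w * 2L^(j - 1L))
  }
  f <- cv(g, d, P, "final3", w)
  out <- cv(g, f, P, "out", cfg$out_channels, k = 1L, relu = FALSE)
  list(main = out, heads = list(out))
}

fw_unetpp <- function(g, x, P, cfg) {
  w <- cfg$base_width
  X <- vector("list", 5L)
  enc <- fw_encoder(g, x, P, w)
  for (i in 1:5) X[[i]] <- list(enc[[i]])          # X[[i]][[j+1]] = node (i, j)
  for (j in 1:4) {
    for (i in 1:(5 - j)) {
      ins <- c(X[[i]][seq_len(j)], list(ag_upsample(g, X[[i + 1]][[j]], 2L)))
      X[[i]][[j + 1]] <- dconv(g, ag_concat(g, ins), P,
                               sprintf("x%d_%d", i, j), w * 2L^(i - 1L))
    }
  }
  heads <- lapply(1:4, function(j)
    cv(g, X[[1]][[j + 1]], P, sprintf("h%d", j), cfg$out_channels,
       k = 1L, relu = FALSE))
  list(main = heads[[4]],
       heads = if (cfg$deep_supervision) heads else heads[4])
}

fw_unet3p <- function(g, x, P, cfg) {
  w <- cfg$base_width
  e <- fw_encoder(g, x, P, w)
  cat_ch <- w                         # per-source channels before fusion
  dec <- vector("list", 5L)
  dec[[5]] <- e[[5]]
  for (j in 4:1) {
    branches <- vector("list", 5L)
    for (s in 1:5) {
      src <- if (s < j) ag_maxpool(g, e[[s]], 2L^(j - s)) else
        if (s == j) e[[j]] else
          ag_upsample(g, if (s == 5L) e[[5]] else dec[[s]], 2L^(s - j))
      branches[[s]] <- cv(g, src, P, sprintf("d%db%d", j, s), cat_ch)
    }
    dec[[j]] <- cv(g, ag_concat(g, branches), P, sprintf("d%df", j), 5L * cat_ch)
  }
  main <- cv(g, dec[[1]], P, "out", cfg$out_channels, k = 1L, relu = FALSE)
  heads <- list(main)
  if (cfg$deep_supervision) {
    for (j in 2:5) {
      h <- cv(g, if (j == 5L) e[[5]] else dec[[j]], P, sprintf("h%d", j),
              cfg$out_channels, k = 1L, relu = FALSE)
      heads[[j]] <- ag_upsample(g, h, 2L^(j - 1L))
    }
  }
  list(main = main, heads = heads)
}

arch_forward <- function(arch) {
  switch(arch, unet = fw_unet, unetpp = fw_unetpp, unet3p = fw_unet3p,
         stop("unknown architecture: ", arch))
}

# Static connection/layer bookkeeping per architecture (depth fixed at 4).
arch_counts <- function(arch) {
  switch(arch,
    unet   = list(maxpool = 4L, upsample = 4L, skips = 4L),
    unetpp = list(maxpool = 4L, upsample = 10L, skips = 20L),
    unet3p = list(maxpool = 10L, upsample = 14L, skips = 16L))
}

#' Build a segmentation model
#'
#' Instantiates the network parameters for the requested architecture by a
#' seeded tracing pass, so identical `(config, init_seed)` pairs give
#' identical weights. [train()] re-initialises parameters from its own
#' `TrainConfig` seed unless told otherwise.
#'
#' @param config a [seg_model_config()].
#' @param init_seed integer seed for He-normal weight initialisation.
#' @return a `seg_model` object (configuration, named parameter arrays, and
#'   layer/connection counts; see [model_layer_counts()]).
#' @export
build_model <- function(config, init_seed = 1L) {
  if (!inherits(config, "seg_model_config")) stop("config must be a seg_model_config")
  store <- new.env(parent = emptyenv())
  store$params <- list()
  withr::with_seed(as.integer(init_seed), {
    g <- ag_graph()
    g$use_norm <- identical(config$norm, "instance")
    x <- ag_input(g, array(0, c(16L, 16L, config$in_channels, 1L)))
    P <- make_param_ctx(g, store, allow_create = TRUE)
    arch_forward(config$arch)(g, x, P, config)
  })
  structure(list(config = config, params = store$params), class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cnt <- model_layer_counts(x)
  cat(sprintf("<seg_model %s> base_width=%d input=%dpx params=%s\n",
              x$config$arch, x$config$base_width, x$config$input_size,
              format(sum(lengths(x$params)), big.mark = ",")))
  cat(sprintf("  layers: %d 3x3 conv, %d 1x1 conv, %d maxpool, %d upsample; %d skip connections\n",
              cnt$conv3, cnt$conv1, cnt$maxpool, cnt$upsample, cnt$skips))
  invisible(x)
}

#' Count layers and skip connections of a model
#'
#' @param model a `seg_model`.
#' @return list with `conv3` (3x3 convolution layers), `conv1` (1x1
#'   convolution layers), `maxpool`, `upsample`, and `skips` (connections that
#'   bypass the sequential encoder-decoder path).
#' @export
model_layer_counts <- function(model) {
  wnames <- grep("\\.w$", names(model$params), value = TRUE)
  ks <- vapply(wnames, function(n) dim(model$params[[n]])[1], 0L)
  c(list(conv3 = sum(ks == 3L), conv1 = sum(ks == 1L)),
    arch_counts(model$config$arch))
}

# Run the network. Returns graph, head logit node ids and the main head id.
model_forward <- function(model, X) {
  stopifnot(length(dim(X)) == 4L, dim(X)[3] == model$config$in_channels)
  g <- ag_graph()
  g$use_norm <- identical(model$config$norm, "instance")
  x <- ag_input(g, X)
  store <- list2env(list(params = model$params), parent = emptyenv())
  P <- make_param_ctx(g, store, allow_create = FALSE)
  out <- arch_forward(model$config$arch)(g, x, P, model$config)
  list(g = g, main = out$main, heads = out$heads, pids = attr(P, "ids"))
}

# Forward pass returning per-channel sigmoid probabilities of the main head,
# shape (H, W, out_channels, N).
predict_probs <- function(model, X) {
  fw <- model_forward(model, X)
  stats::plogis(ag_value(fw$g, fw$main))
}

# One loss evaluation + gradient for a batch: deep-supervision head losses are
# averaged with equal weights. Returns list(loss, grads named by parameter).
model_loss_grads <- function(model, X, Y) {
  fw <- model_forward(model, X)
  losses <- lapply(fw$heads, function(h) ag_bce_logits(fw$g, h, Y))
  loss <- ag_mean_scalars(fw$g, losses)
  grads <- ag_backward(fw$g, loss)
  pn <- ls(fw$pids)
  out <- stats::setNames(lapply(pn, function(n) {
    gr <- grads[[fw$pids[[n]]]]
    if (is.null(gr)) {
      p <- model$params[[n]]
      if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
    } else gr
  }), pn)
  list(loss = ag_value(fw$g, loss), grads = out)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS files holding the parameter arrays together with the
#' model configuration serialised as JSON, so a checkpoint is self-describing.
#'
#' @param model a `seg_model`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `seg_model`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(config_json = jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE),
              params = model$params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- jsonlite::fromJSON(obj$config_json)
  config <- seg_model_config(arch = cfg$arch, base_width = cfg$base_width,
                             input_size = cfg$input_size,
                             in_channels = cfg$in_channels,
                             out_channels = cfg$out_channels,
                             deep_supervision = cfg$deep_supervision,
                             norm = cfg$norm %||% "none")
  structure(list(config = config, params = obj$params), class = "seg_model")
}
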