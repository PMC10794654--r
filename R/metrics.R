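#' Pixelwise segmentation metrics
#'
#' Precision, recall, F1 and IoU between a predicted and a true binary mask.
#' IoU is computed exactly as tp / (tp + fp + fn). Degenerate denominators
#' follow fixed conventions so cross-validation on synthetic corner cases
#' cannot crash: an empty prediction against an empty truth scores 1 on every
#' metric; an empty denominator with a non-empty counterpart scores 0.
#'
#' @param pred,truth binary masks of identical dimensions.
#' @return list with `precision`, `recall`, `f1`, `iou`, `tp`, `fp`, `fn`.
#' @export
seg_metrics <- function(pred, truth) {
  p <- as_binary_matrix(pred)
  t_ <- as_binary_matrix(truth)
  if (!identical(dim(p), dim(t_))) stop("seg_metrics: mask dimensions differ")
  tp <- sum(p == 1L & t_ == 1L)
  fp <- sum(p == 1L & t_ == 0L)
  fn <- sum(p == 0L & t_ == 1L)
  precision <- if (tp + fp == 0L) (if (fn == 0L) 1 else 0) else tp / (tp + fp)
  recall    <- if (tp + fn == 0L) (if (fp == 0L) 1 else 0) else tp / (tp + fn)
  f1  <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  iou <- if (tp + fp + fn == 0L) 1 else tp / (tp + fp + fn)
  list(precision = precision, recall = recall, f1 = f1, iou = iou,
       tp = tp, fp = fp, fn = fn)
}

#' Mean binary cross-entropy of predicted probabilities
#'
#' The training objective evaluated on probabilities: with N the total pixel
#' count over both region channels, r the 0/1 annotation and p the predicted
#' probability, CE = -(1/N) * sum( r log p + (1 - r) log(1 - p) ).
#' Probabilities are clamped to \[eps, 1 - eps\].
#'
#' @param pred_probs array (H, W, 2) of probabilities in (0, 1).
#' @param target list of two binary masks `(pupil, tz)` or an (H, W, 2) array.
#' @param eps clamping constant.
#' @return nonnegative scalar loss.
#' @export
ce_loss <- function(pred_probs, target, eps = 1e-7) {
  if (is.list(target)) {
    target <- array(c(as_binary_matrix(target[[1]]), as_binary_matrix(target[[2]])),
                    c(dim(target[[1]]), 2L))
  }
  if (!identical(dim(pred_probs)[1:3], dim(target)[1:3]))
    stop("ce_loss: prediction and target shapes differ")
  p <- pmin(pmax(pred_probs, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

# Mean per-region metrics of a model over a list of cases (native-resolution
# evaluation through predict_masks).
evaluate_cases <- function(model, cases, threshold = 0.5,
                           mask_resize = c("bilinear", "nearest"),
                           tta = FALSE) {
  mask_resize <- match.arg(mask_resize)
  per <- lapply(cases, function(cs) {
    pr <- predict_masks(model, cs$image, threshold = threshold,
                        mask_resize = mask_resize, tta = tta)
    list(pupil = seg_metrics(pr$pupil, cs$pupil_mask),
         tz = seg_metrics(pr$tz, cs$tz_mask))
  })
  agg <- function(region, field)
    mean(vapply(per, function(x) x[[region]][[field]], 0))
  data.frame(
    region = c("pupil", "treatment_zone"),
    precision = c(agg("pupil", "precision"), agg("tz", "precision")),
    recall = c(agg("pupil", "recall"), agg("tz", "recall")),
    f1 = c(agg("pupil", "f1"), agg("tz", "f1")),
    iou = c(agg("pupil", "iou"), agg("tz", "iou")))
}

#' K-fold cross-validation of a segmentation configuration
#'
#' Shuffles the dataset with the training seed, splits it into `k` disjoint
#' folds, trains a fresh model on the other k - 1 folds for each fold in turn
#' and evaluates on the held-out fold. `mode = "repeated"` instead draws `k`
#' independent random (k-1)/k splits, mirroring the alternative protocol of
#' repeated random subsampling.
#'
#' @param dataset list of cases (each with `image`, `pupil_mask`, `tz_mask`).
#' @param k number of folds (default 10).
#' @param model_cfg a [seg_model_config()].
#' @param train_cfg a [train_config()]; its seed drives the fold shuffle.
#' @param mode `"kfold"` (disjoint folds) or `"repeated"` (random resplits).
#' @return list with `per_fold` (data.frame, one row per fold and region, in
#'   the column order precision / recall / f1 / iou), `mean` (aggregate over
#'   folds), and `folds` (the validation index sets).
#' @export
kfold_evaluate <- function(dataset, k = 10L, model_cfg, train_cfg,
                           mode = c("kfold", "repeated")) {
  mode <- match.arg(mode)
  n <- length(dataset)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k exceeds the dataset size")
  folds <- withr::with_seed(train_cfg$seed, {
    if (mode == "kfold") {
      idx <- sample.int(n)
      unname(split(idx, rep_len(seq_len(k), n)))
    } else {
      lapply(seq_len(k), function(i) sample.int(n, size = max(1L, round(n / k))))
    }
  })
  rows <- list()
  for (i in seq_len(k)) {
    val <- folds[[i]]
    tr <- train(dataset[setdiff(seq_len(n), val)],
                build_model(model_cfg, init_seed = train_cfg$seed + i),
                modify_train_config(train_cfg, seed = train_cfg$seed + i),
                val_fraction = 0)
    m <- evaluate_cases(tr$model, dataset[val])
    m$fold <- i
    rows[[i]] <- m
  }
  per_fold <- do.call(rbind, rows)[, c("fold", "region", "precision",
                                       "recall", "f1", "iou")]
  mn <- stats::aggregate(per_fold[, c("precision", "recall", "f1", "iou")],
                         by = list(region = per_fold$region), FUN = mean)
  list(per_fold = per_fold, mean = mn, folds = folds)
}
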