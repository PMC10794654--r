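# End-to-end orchestration: generate / train / evaluate / grade, with a
# single config (R list, YAML or JSON file), seeded reproducibility and
# per-record error isolation in grade mode. The learned path (network masks)
# and the oracle path (ground-truth masks, `use_gt_masks`) share all
# post-segmentation code, so any disagreement between them is attributable to
# segmentation alone.

#' Assemble a pipeline configuration
#'
#' @param mode one of `"generate"`, `"train"`, `"evaluate"`, `"grade"`.
#' @param out_dir output directory.
#' @param manifest dataset manifest path (JSONL, see [write_dataset()]).
#' @param checkpoint model checkpoint path.
#' @param n number of cases (generate mode).
#' @param seed integer seed.
#' @param arch,base_width,input_size model settings (see
#'   [seg_model_config()]).
#' @param learning_rate,batch_size,epochs training settings (see
#'   [train_config()]).
#' @param px_per_mm physical scale used for grading.
#' @param k_folds if > 0, run K-fold cross-validation in evaluate mode.
#' @param use_gt_masks grade from the manifest's ground-truth masks instead
#'   of the network (the oracle path).
#' @param threshold probability cut-off for [predict_masks()].
#' @param tta test-time augmentation for [predict_masks()].
#' @param param_ranges generator ranges (see [default_param_ranges()]).
#' @param log_level `"info"`, `"warning"` or `"quiet"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("generate", "train", "evaluate", "grade"),
                            out_dir = ".", manifest = NULL, checkpoint = NULL,
                            n = 100L, seed = 0L, arch = "unet3p",
                            base_width = 8L, input_size = 64L,
                            learning_rate = 1e-4, batch_size = 16L,
                            epochs = 40L, px_per_mm = 50, k_folds = 0L,
                            use_gt_masks = FALSE, threshold = 0.5,
                            tta = TRUE, param_ranges = list(),
                            log_level = "info") {
  mode <- match.arg(mode)
  structure(list(mode = mode, out_dir = out_dir, manifest = manifest,
                 checkpoint = checkpoint, n = as.integer(n),
                 seed = as.integer(seed), arch = arch,
                 base_width = as.integer(base_width),
                 input_size = as.integer(input_size),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), px_per_mm = px_per_mm,
                 k_folds = as.integer(k_folds),
                 use_gt_masks = isTRUE(use_gt_masks), threshold = threshold,
                 tta = isTRUE(tta), param_ranges = param_ranges,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path config file; keys mirror the arguments of
#'   [pipeline_config()].
#' @param ... overrides applied on top of the file (CLI flags).
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyVector = TRUE)
  vals <- utils::modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}

plog <- function(cfg, level, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  if (identical(cfg$log_level, "warning") && level == "info") return(invisible())
  msg <- sprintf("[%s] %s", level, sprintf(fmt, ...))
  message(msg)
  lf <- file.path(cfg$out_dir, "run.log")
  if (dir.exists(cfg$out_dir)) cat(msg, "\n", file = lf, append = TRUE)
  invisible()
}

config_provenance <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(js, tf)
  on.exit(unlink(tf))
  list(config_hash = unname(tools::md5sum(tf)), seed = cfg$seed,
       version = as.character(utils::packageVersion("oktopo")))
}

model_cfg_of <- function(cfg) {
  seg_model_config(arch = cfg$arch, base_width = cfg$base_width,
                   input_size = cfg$input_size)
}

train_cfg_of <- function(cfg) {
  train_config(learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
               epochs = cfg$epochs, input_size_px = cfg$input_size,
               seed = cfg$seed)
}

#' Run the pipeline
#'
#' Executes one mode:
#' \describe{
#'   \item{generate}{synthetic dataset + JSONL manifest in `out_dir`.}
#'   \item{train}{train on the manifest dataset; writes `checkpoint.rds` and
#'     `loss_history.csv`.}
#'   \item{evaluate}{held-out metrics CSV per region (precision / recall /
#'     f1 / iou); with `k_folds > 0` additionally a per-fold
#'     cross-validation table.}
#'   \item{grade}{per-image JSONL report with mask areas, indicators and the
#'     topography class; an image whose segmentation is ungradable is flagged
#'     (with the failing region) and the run continues.}
#' }
#' Every run writes `provenance.json` (config hash, seed, package version).
#'
#' @param cfg a `pipeline_config`, or a path to a YAML/JSON config file.
#' @param ... overrides when `cfg` is a path.
#' @return mode-dependent: the dataset, the training result, the metrics
#'   table, or the grade report (a list of per-image records plus summary).
#' @export
run_pipeline <- function(cfg, ...) {
  if (is.character(cfg)) cfg <- load_pipeline_config(cfg, ...)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- config_provenance(cfg)
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE),
             file.path(cfg$out_dir, "provenance.json"))
  switch(cfg$mode,
    generate = {
      plog(cfg, "info", "generating %d synthetic cases (seed %d)", cfg$n, cfg$seed)
      cases <- generate_dataset(cfg$n, cfg$param_ranges, seed = cfg$seed)
      mf <- write_dataset(cases, cfg$out_dir)
      plog(cfg, "info", "manifest written: %s", mf)
      invisible(cases)
    },
    train = {
      if (is.null(cfg$manifest)) stop("train mode needs a manifest")
      dataset <- read_dataset(cfg$manifest)
      model <- build_model(model_cfg_of(cfg), init_seed = cfg$seed)
      res <- train(dataset, model, train_cfg_of(cfg))
      ck <- cfg$checkpoint %||% file.path(cfg$out_dir, "checkpoint.rds")
      save_checkpoint(res$model, ck)
      utils::write.csv(data.frame(epoch = seq_along(res$history),
                                  loss = res$history),
                       file.path(cfg$out_dir, "loss_history.csv"),
                       row.names = FALSE)
      plog(cfg, "info", "checkpoint written: %s (final loss %.5f)",
           ck, utils::tail(res$history, 1))
      invisible(res)
    },
    evaluate = {
      if (is.null(cfg$manifest)) stop("evaluate mode needs a manifest")
      dataset <- read_dataset(cfg$manifest)
      if (cfg$k_folds > 0L) {
        cv <- kfold_evaluate(dataset, k = cfg$k_folds, model_cfg_of(cfg),
                             train_cfg_of(cfg))
        utils::write.csv(cv$per_fold, file.path(cfg$out_dir, "kfold_metrics.csv"),
                         row.names = FALSE)
        utils::write.csv(cv$mean, file.path(cfg$out_dir, "kfold_mean.csv"),
                         row.names = FALSE)
        invisible(cv)
      } else {
        if (is.null(cfg$checkpoint)) stop("evaluate mode needs a checkpoint")
        model <- load_checkpoint(cfg$checkpoint)
        m <- evaluate_cases(model, dataset, threshold = cfg$threshold,
                            tta = cfg$tta)
        utils::write.csv(m, file.path(cfg$out_dir, "seg_metrics.csv"),
                         row.names = FALSE)
        invisible(m)
      }
    },
    grade = grade_mode(cfg))
}

grade_mode <- function(cfg) {
  if (is.null(cfg$manifest)) stop("grade mode needs a manifest")
  dataset <- read_dataset(cfg$manifest)
  model <- NULL
  if (!cfg$use_gt_masks) {
    if (is.null(cfg$checkpoint)) stop("grade mode needs a checkpoint (or use_gt_masks)")
    model <- load_checkpoint(cfg$checkpoint)
  }
  records <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    cs <- dataset[[i]]
    rec <- tryCatch({
      masks <- if (cfg$use_gt_masks)
        list(pupil = cs$pupil_mask, tz = cs$tz_mask)
      else predict_masks(model, cs$image, threshold = cfg$threshold,
                         tta = cfg$tta)
      ind <- compute_indicators(masks$pupil, masks$tz, px_per_mm = cfg$px_per_mm)
      cl <- classify(ind)
      list(index = i, ungradable = FALSE,
           pupil_area_px = sum(as_binary_matrix(masks$pupil)),
           tz_area_px = sum(as_binary_matrix(masks$tz)),
           indicators = unclass(ind), class = as.character(cl),
           rule_fired = attr(cl, "rule_fired"),
           true_class = cs$true_class)
    }, oktopo_ungradable = function(e) {
      plog(cfg, "warning", "case %d ungradable (%s): %s", i,
           e$region, conditionMessage(e))
      list(index = i, ungradable = TRUE, reason = conditionMessage(e),
           region = e$region, true_class = cs$true_class)
    }, error = function(e) {
      plog(cfg, "warning", "case %d failed: %s", i, conditionMessage(e))
      list(index = i, ungradable = TRUE, reason = conditionMessage(e),
           region = NA_character_, true_class = cs$true_class)
    })
    records[[i]] <- rec
  }
  out <- file.path(cfg$out_dir, "grade_report.jsonl")
  con <- file(out, open = "w")
  for (r in records)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, na = "null"), con)
  close(con)
  truth <- vapply(records, function(r) r$true_class %||% NA_character_, "")
  pred <- vapply(records, function(r)
    if (isTRUE(r$ungradable)) NA_character_ else r$class, "")
  summary <- list(n = length(records),
                  n_ungradable = sum(vapply(records, function(r)
                    isTRUE(r$ungradable), TRUE)),
                  class_distribution = table(factor(pred, levels = topo_levels)))
  if (!all(is.na(truth))) {
    ok <- !is.na(pred) & pred == truth
    summary$accuracy <- mean(ok[!is.na(truth)])
  }
  plog(cfg, "info", "graded %d images (%d ungradable)%s", summary$n,
       summary$n_ungradable,
       if (!is.null(summary$accuracy))
         sprintf(", accuracy %.3f", summary$accuracy) else "")
  invisible(list(records = records, summary = summary, report_path = out))
}
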