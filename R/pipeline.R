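# End-to-end orchestration: simulate -> train -> explain -> evaluate.
# Each command wraps the module functions, reads/writes only declared
# formats (PNG, YAML, JSON, JSONL, CSV), and honors the global seed.

log_msg <- function(config, ...) {
  if (identical(config$log_level %||% "info", "quiet")) return(invisible())
  message(sprintf(...))
}

#' Generate a synthetic dataset on disk
#'
#' Wraps [generate_synthetic_dataset()] and [write_image_folder()]: writes
#' the class-per-folder PNG tree plus the JSON truth sidecar.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param out_dir output dataset directory.
#' @param force overwrite an existing non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
cmd_simulate <- function(config, out_dir, force = FALSE) {
  config <- validate_config(config)
  spec <- config_fixture_spec(config)
  samples <- generate_synthetic_dataset(spec)
  if (length(samples) == 0) {
    warning("n_per_class = 0: writing empty class folders")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cls in seq_len(spec$n_classes) - 1L) {
      dir.create(file.path(out_dir, sprintf("class_%02d", cls)),
                 showWarnings = FALSE)
    }
    return(invisible(out_dir))
  }
  write_image_folder(samples, out_dir, spec = spec, force = force)
  log_msg(config, "[simulate] wrote %d images (%d classes) to %s",
          length(samples), spec$n_classes, out_dir)
  invisible(out_dir)
}

#' Train the backbone on a dataset directory
#'
#' @param config a `run_config`.
#' @param data_dir class-per-folder dataset (see [load_image_folder()]).
#' @param checkpoint_path output checkpoint (JSON).
#' @param history_path optional CSV of the per-epoch loss history.
#' @return the trained [backbone_model()], invisibly.
#' @export
cmd_train <- function(config, data_dir, checkpoint_path,
                      history_path = NULL) {
  config <- validate_config(config)
  samples <- load_image_folder(data_dir,
                               patch_size = config$distortion$patch_size)
  d <- dim(samples[[1]]$pixels)
  n_classes <- length(unique(vapply(samples, function(s) s$label, integer(1))))
  model <- backbone_model(d, n_classes, channels = config$backbone$channels,
                          seed = derive_seed(config$seed, 23L))
  tcfg <- config_train(config)
  model <- train_supervised(model, samples, tcfg)
  save_checkpoint(model, checkpoint_path)
  if (!is.null(history_path)) {
    utils::write.csv(model$history, history_path, row.names = FALSE)
  }
  n_hist <- nrow(model$history)
  log_msg(config,
          "[train] %d epoch(s), final train acc %.3f, checkpoint %s",
          n_hist, if (n_hist > 0) model$history$train_acc[n_hist] else NA,
          checkpoint_path)
  invisible(model)
}

#' Attack and explain a set of images
#'
#' Runs one RL episode per image against the checkpointed backbone, writes
#' per-image saliency mask PNGs, a JSONL trace (one step per line), and a
#' JSON summary per image (success flag, D before/after cleanup, distorted
#' patch counts, localization enrichment when truth is available) plus an
#' aggregate summary.
#'
#' @param config a `run_config`.
#' @param checkpoint_path backbone checkpoint from [cmd_train()].
#' @param data_dir dataset directory; ground-truth regions are reattached
#'   from the sidecar when present.
#' @param out_dir output directory for masks and traces.
#' @param max_images cap on the number of images attacked (NULL = all).
#' @param do_cleanup run [cleanup_episode()] on successful episodes.
#' @return the aggregate summary list, invisibly.
#' @export
cmd_explain <- function(config, checkpoint_path, data_dir, out_dir,
                        max_images = NULL, do_cleanup = TRUE) {
  config <- validate_config(config)
  model <- load_checkpoint(checkpoint_path)
  samples <- load_image_folder(data_dir,
                               patch_size = config$distortion$patch_size)
  if (!is.null(max_images)) {
    samples <- samples[seq_len(min(max_images, length(samples)))]
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bb <- as_blackbox(model)
  filter <- config_filter(config)
  qcfg <- config_qcfg(config)
  rcfg <- config_rcfg(config)
  res <- run_attack(bb, samples, filter, qcfg, rcfg,
                    patch_size = config$distortion$patch_size)
  trace_path <- file.path(out_dir, "traces.jsonl")
  con <- file(trace_path, open = "wt")
  on.exit(close(con), add = TRUE)
  records <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    ep <- res$episodes[[i]]
    s <- samples[[i]]
    grid <- segment_patches(s, config$distortion$patch_size)
    d_before <- state_distance(ep$state)
    n_before <- length(distorted_patches(ep$state))
    cleaned <- ep$state
    if (do_cleanup && ep$success && ep$steps > 0) {
      cleaned <- cleanup_episode(bb, ep)
    }
    mask <- compute_mask(s$pixels, cleaned$current, grid, episode_id = s$id)
    write_heatmap(mask$values, file.path(out_dir, paste0(s$id, "_mask.png")))
    enrich <- if (!is.null(s$truth_region) && max(mask$values) > 0) {
      localization_enrichment(mask, s$truth_region)
    } else NA_real_
    if (ep$steps > 0) {
      for (r in seq_len(nrow(ep$trajectory))) {
        writeLines(jsonlite::toJSON(
          c(list(image = s$id), as.list(ep$trajectory[r, ])),
          auto_unbox = TRUE, digits = NA), con)
      }
    }
    records[[i]] <- list(
      image = s$id, label = s$label, success = ep$success,
      steps = ep$steps, queries = ep$queries,
      d_before_cleanup = d_before, d_after_cleanup = state_distance(cleaned),
      patches_before_cleanup = n_before,
      patches_after_cleanup = length(distorted_patches(cleaned)),
      enrichment = enrich)
  }
  successes <- vapply(records, function(r) r$success, logical(1))
  summary <- list(
    n_images = length(records),
    n_success = sum(successes),
    success_rate = mean(successes),
    mean_enrichment = mean(vapply(records, function(r) r$enrichment,
                                  numeric(1)), na.rm = TRUE),
    images = records)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  log_msg(config, "[explain] %d/%d episodes succeeded; outputs in %s",
          summary$n_success, summary$n_images, out_dir)
  invisible(summary)
}

#' Evaluate a checkpoint on a dataset
#'
#' Writes the per-class and macro six-statistic metrics report as JSON and
#' an aligned text table, plus the per-image prediction CSV from which the
#' metrics are recomputable.
#'
#' @param config a `run_config`.
#' @param checkpoint_path backbone checkpoint.
#' @param data_dir dataset directory.
#' @param out_dir output directory.
#' @return the metrics list, invisibly.
#' @export
cmd_evaluate <- function(config, checkpoint_path, data_dir, out_dir) {
  config <- validate_config(config)
  model <- load_checkpoint(checkpoint_path)
  samples <- load_image_folder(data_dir,
                               patch_size = config$distortion$patch_size)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  probs <- predict_proba_batch(model, samples)
  pred <- max.col(probs) - 1L
  truth <- vapply(samples, function(s) s$label, integer(1))
  pred_df <- data.frame(
    image = vapply(samples, function(s) s$id, character(1)),
    true_label = truth, predicted_label = pred)
  for (k in seq_len(ncol(probs))) {
    pred_df[[sprintf("p_class_%02d", k - 1L)]] <- probs[, k]
  }
  utils::write.csv(pred_df, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  mm <- metrics_macro(truth, pred,
                      g_means_as_printed = config$metrics$g_means_as_printed)
  report <- list(per_class = lapply(mm$per_class, unclass),
                 macro = as.list(mm$macro))
  jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  tbl <- format_metrics_table(c(mm$per_class, list(macro = as.list(mm$macro))))
  writeLines(tbl, file.path(out_dir, "metrics.txt"))
  log_msg(config, "[evaluate] macro accuracy %.4f; reports in %s",
          mm$macro[["accuracy"]], out_dir)
  invisible(mm)
}
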