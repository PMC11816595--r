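# Run configuration: one nested, fully serializable list drives every
# pipeline stage, so a saved config plus its seed reproduces all
# deterministic outputs.

#' Default run configuration
#'
#' Nested sections for the synthetic fixtures, backbone training, the
#' distortion filter, the RL agent, and evaluation. Values can be
#' overridden by a YAML file ([load_config()]) or programmatically.
#'
#' @param seed global seed; section seeds are derived from it.
#' @return a nested `run_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    fixtures = list(
      n_classes = 2L, n_per_class = 30L, image_size = c(16L, 16L),
      channels = 1L, background = 0.5, background_noise_sd = 0.02),
    backbone = list(
      channels = c(8L, 16L), learning_rate = 0.001, weight_decay = 1e-4,
      batch_size = 32L, max_epochs = 100L, early_stopping_patience = 10L,
      val_fraction = 0.2,
      augment = list(rotations = FALSE, flips = FALSE, brightness = FALSE,
                     noise_sd = 0)),
    distortion = list(
      kind = "gaussian_noise", noise_sd = 0.1, brightness = 0.1,
      blur_sd = 0.5, patch_size = 2L),
    rl = list(
      p_max = 8L, max_steps = 50L, gamma = 0.9, q_learning_rate = 0.1,
      eps_start = 1.0, eps_end = 0.05, eps_decay = 0.9,
      bins = c(4L, 4L, 4L, 4L), d_scale = 2.0, sens_scale = 0.2,
      reward_mode = "pd_ratio", alpha = 1, beta = 1, l2_floor = 1e-8,
      r_max = 1e6),
    metrics = list(g_means_as_printed = FALSE, positive_class = 1L)),
    class = "run_config")
}

#' Load / save a run configuration as YAML
#'
#' Loading starts from [default_config()] and overlays the YAML values, so
#' partial configs are valid.
#'
#' @param path YAML file path.
#' @param config a `run_config` list (for saving).
#' @return the merged `run_config` (`load_config`); `path` invisibly
#'   (`save_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) config_stop(sprintf("config file '%s' not found", path))
  user <- tryCatch(yaml::read_yaml(path), error = function(e) {
    config_stop(sprintf("cannot parse config '%s': %s", path,
                        conditionMessage(e)))
  })
  validate_config(merge_config(default_config(), user))
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass_recursive(config), path)
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

merge_config <- function(base, user) {
  if (!is.list(user)) return(user)
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
                      !is.null(names(base[[nm]]))) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

#' Validate a run configuration
#'
#' Cross-field checks at pipeline entry: the image size must be divisible
#' by the patch size, the distortion filter must be minimal (a single
#' application moves the image L2 norm by less than 5% of the image norm on
#' a reference fixture image), and every section must construct cleanly.
#'
#' @param config a `run_config` list.
#' @return the config, invisibly classed, or a config error.
#' @export
validate_config <- function(config) {
  fx <- config$fixtures
  if (any(fx$image_size %% config$distortion$patch_size != 0)) {
    config_stop(sprintf(
      "image_size %s is not divisible by distortion patch_size %d",
      paste(fx$image_size, collapse = "x"), config$distortion$patch_size))
  }
  spec <- config_fixture_spec(config)     # validates fixture params
  qcfg <- config_qcfg(config)             # validates RL params
  rcfg <- config_rcfg(config)
  ref <- generate_synthetic_dataset(
    synthetic_spec(n_per_class = 1L, image_size = fx$image_size,
                   channels = fx$channels, background = fx$background,
                   background_noise_sd = fx$background_noise_sd,
                   seed = config$seed))[[1]]
  grid <- segment_patches(ref, config$distortion$patch_size)
  validate_filter_strength(config_filter(config), ref, grid)
  invisible(structure(config, class = "run_config"))
}

config_fixture_spec <- function(config) {
  fx <- config$fixtures
  synthetic_spec(n_classes = fx$n_classes, n_per_class = fx$n_per_class,
                 image_size = fx$image_size, channels = fx$channels,
                 class_feature_params = fx$class_feature_params,
                 background = fx$background,
                 background_noise_sd = fx$background_noise_sd,
                 seed = derive_seed(config$seed, 11L))
}

config_filter <- function(config) {
  dz <- config$distortion
  distortion_filter(kind = dz$kind, noise_sd = dz$noise_sd,
                    brightness = dz$brightness, blur_sd = dz$blur_sd,
                    seed = derive_seed(config$seed, 13L))
}

config_train <- function(config) {
  bk <- config$backbone
  train_config(learning_rate = bk$learning_rate,
               weight_decay = bk$weight_decay, batch_size = bk$batch_size,
               max_epochs = bk$max_epochs,
               early_stopping_patience = bk$early_stopping_patience,
               val_fraction = bk$val_fraction, augment = bk$augment,
               seed = derive_seed(config$seed, 17L))
}

config_qcfg <- function(config) {
  rl <- config$rl
  qlearning_config(gamma = rl$gamma, q_learning_rate = rl$q_learning_rate,
                   eps_start = rl$eps_start, eps_end = rl$eps_end,
                   eps_decay = rl$eps_decay, max_steps = rl$max_steps,
                   p_max = rl$p_max, bins = rl$bins, d_scale = rl$d_scale,
                   sens_scale = rl$sens_scale,
                   seed = derive_seed(config$seed, 19L))
}

config_rcfg <- function(config) {
  rl <- config$rl
  reward_config(mode = rl$reward_mode, alpha = rl$alpha, beta = rl$beta,
                l2_floor = rl$l2_floor, r_max = rl$r_max)
}
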