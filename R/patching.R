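# Patch grid segmentation, bounded per-patch distortion filters, the evolving
# perturbation state, and per-patch sensitivity of the ground-truth
# probability.

#' Segment an image into an n x n patch grid
#'
#' @param image an [image_sample()], image array, or integer `c(H, W)`.
#' @param n patch side length in pixels; must divide both H and W exactly.
#' @return object of class `patch_grid` with `rows = H/n`, `cols = W/n`;
#'   patches are indexed row-major, 0-based.
#' @export
segment_patches <- function(image, n) {
  if (inherits(image, "image_sample")) {
    d <- dim(image$pixels)[1:2]
  } else if (is.array(image) || is.matrix(image)) {
    d <- dim(image)[1:2]
  } else {
    d <- as.integer(image)
  }
  n <- as.integer(n)
  if (n < 1L) config_stop("patch size n must be >= 1")
  if (d[1] %% n != 0L || d[2] %% n != 0L) {
    config_stop(sprintf(
      "patch size %d does not divide image dimensions %dx%d", n, d[1], d[2]))
  }
  structure(list(n = n, H = d[1], W = d[2],
                 rows = d[1] %/% n, cols = d[2] %/% n,
                 n_patches = (d[1] %/% n) * (d[2] %/% n)),
            class = "patch_grid")
}

#' Pixel extent of one patch
#'
#' @param grid a [segment_patches()] grid.
#' @param k 0-based patch index (row-major).
#' @return list with 1-based pixel index vectors `rows` and `cols`.
#' @export
patch_pixels <- function(grid, k) {
  k <- as.integer(k)
  if (k < 0L || k >= grid$n_patches) {
    rls_stop(sprintf("patch index %d out of range [0, %d)", k, grid$n_patches))
  }
  r <- k %/% grid$cols
  c_ <- k %% grid$cols
  list(rows = r * grid$n + seq_len(grid$n),
       cols = c_ * grid$n + seq_len(grid$n))
}

#' A bounded per-patch distortion filter
#'
#' One of three small, fixed-strength corruptions applied to a single patch:
#' zero-mean Gaussian pixel noise, a constant brightness offset, or a
#' Gaussian blur confined to the patch. Strengths are held constant across
#' all patches within a run and are meant to be minimal so each application
#' perturbs the image only incrementally.
#'
#' @param kind `"gaussian_noise"`, `"brightness"`, or `"blur"`.
#' @param noise_sd standard deviation of the Gaussian noise.
#' @param brightness additive offset.
#' @param blur_sd Gaussian blur kernel standard deviation (pixels); 0 is the
#'   identity.
#' @param seed base seed of the per-(patch, application-count) noise stream,
#'   making every application reproducible and exactly removable.
#' @return object of class `distortion_filter`.
#' @export
distortion_filter <- function(kind = c("gaussian_noise", "brightness", "blur"),
                              noise_sd = 0.1, brightness = 0.1, blur_sd = 0.5,
                              seed = 0L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, noise_sd = noise_sd, brightness = brightness,
                 blur_sd = blur_sd, seed = as.integer(seed)),
            class = "distortion_filter")
}

#' Check that a filter is minimal on a reference image
#'
#' A single application must change the image L2 norm by less than 5% of the
#' image norm; stronger settings defeat the incremental-perturbation design.
#'
#' @param filter a [distortion_filter()].
#' @param image reference image array or [image_sample()].
#' @param grid a [segment_patches()] grid for the image.
#' @return `TRUE` invisibly; raises a config error otherwise.
#' @export
validate_filter_strength <- function(filter, image, grid) {
  img <- if (inherits(image, "image_sample")) image$pixels else
    as_image_array(image)
  st <- perturbation_state(image_sample(img, 0L), grid, filter)
  st1 <- apply_distortion(st, 0L)
  if (state_distance(st1) >= 0.05 * sqrt(sum(img^2))) {
    config_stop(sprintf(
      "distortion filter is not minimal: one application moved L2 by %.4f, >= 5%% of the image norm %.4f",
      state_distance(st1), sqrt(sum(img^2))))
  }
  invisible(TRUE)
}

# Apply a filter to one patch block (n x n x C array). Noise draws are a pure
# function of (filter seed, patch index, application count).
filter_apply_block <- function(block, filter, patch_index, count) {
  out <- switch(
    filter$kind,
    gaussian_noise = {
      if (filter$noise_sd > 0) {
        noise <- with_seed(
          derive_seed(filter$seed, patch_index + 1L, count),
          stats::rnorm(length(block), 0, filter$noise_sd))
        block + array(noise, dim = dim(block))
      } else block
    },
    brightness = block + filter$brightness,
    blur = {
      if (filter$blur_sd > 0) blur_block(block, filter$blur_sd) else block
    })
  clip01(out)
}

# Separable Gaussian blur within the patch, edge-replicated.
blur_block <- function(block, sd) {
  n <- dim(block)[1]
  off <- -(n - 1):(n - 1)
  w <- stats::dnorm(off, 0, sd)
  idx <- seq_len(n)
  K <- outer(idx, idx, function(a, b) w[a - b + n])
  K <- K / rowSums(K)
  out <- block
  for (ch in seq_len(dim(block)[3])) {
    out[, , ch] <- K %*% block[, , ch] %*% t(K)
  }
  out
}

#' Initialize a perturbation state
#'
#' The evolving distorted image together with per-patch distortion counters,
#' the L2 distance `D` to the original, per-patch LIFO snapshots enabling
#' bit-exact removal, and the step index.
#'
#' @param sample an [image_sample()] (the original image).
#' @param grid a [segment_patches()] grid matching the image.
#' @param filter the [distortion_filter()] used for all applications.
#' @return object of class `perturbation_state` (value semantics: operations
#'   return modified copies).
#' @export
perturbation_state <- function(sample, grid, filter) {
  img <- sample$pixels
  if (dim(img)[1] != grid$H || dim(img)[2] != grid$W) {
    data_stop(sprintf("image %dx%d does not match grid %dx%d",
                      dim(img)[1], dim(img)[2], grid$H, grid$W))
  }
  structure(
    list(original = img, current = img,
         counts = integer(grid$n_patches),
         stacks = vector("list", grid$n_patches),
         grid = grid, filter = filter,
         t = 0L, n_ops = 0L, label = sample$label, id = sample$id,
         truth_region = sample$truth_region),
    class = "perturbation_state")
}

#' L2 distance of the current image from the original
#'
#' @param state a [perturbation_state()].
#' @return Euclidean norm of the accumulated perturbation.
#' @export
state_distance <- function(state) {
  sqrt(sum((state$current - state$original)^2))
}

#' Total outstanding distortion applications
#'
#' @param state a [perturbation_state()].
#' @return sum of the per-patch distortion counters.
#' @export
distortion_total <- function(state) sum(state$counts)

#' Indices of currently distorted patches
#'
#' @param state a [perturbation_state()].
#' @return 0-based indices of patches with at least one distortion.
#' @export
distorted_patches <- function(state) which(state$counts > 0L) - 1L

#' Apply one distortion to a patch
#'
#' Only pixels inside the patch change; the result is clipped to `[0,1]`.
#' The pre-application patch pixels are pushed on the patch's LIFO stack, so
#' [remove_distortion()] restores the prior image bit-exactly. Noise draws
#' come from a deterministic per-(patch, application-count) seed stream.
#'
#' @param state a [perturbation_state()].
#' @param patch_index 0-based patch index.
#' @param filter filter to apply; defaults to the state's filter.
#' @return the updated state.
#' @export
apply_distortion <- function(state, patch_index, filter = state$filter) {
  px <- patch_pixels(state$grid, patch_index)
  k1 <- as.integer(patch_index) + 1L
  old_block <- state$current[px$rows, px$cols, , drop = FALSE]
  new_block <- filter_apply_block(old_block, filter, as.integer(patch_index),
                                  state$counts[k1] + 1L)
  state$stacks[[k1]] <- c(state$stacks[[k1]], list(old_block))
  state$counts[k1] <- state$counts[k1] + 1L
  state$current[px$rows, px$cols, ] <- new_block
  state$n_ops <- state$n_ops + 1L
  state
}

#' Undo the most recent distortion on a patch
#'
#' LIFO per patch: the stored pre-application pixels are replayed, making
#' removal exact rather than arithmetic inversion.
#'
#' @param state a [perturbation_state()].
#' @param patch_index 0-based patch index with distortion count `>= 1`.
#' @return the updated state.
#' @export
remove_distortion <- function(state, patch_index) {
  k1 <- as.integer(patch_index) + 1L
  if (k1 < 1L || k1 > state$grid$n_patches || state$counts[k1] < 1L) {
    rls_stop(sprintf("cannot remove a distortion from patch %d: none applied",
                     as.integer(patch_index)))
  }
  px <- patch_pixels(state$grid, patch_index)
  depth <- length(state$stacks[[k1]])
  state$current[px$rows, px$cols, ] <- state$stacks[[k1]][[depth]]
  state$stacks[[k1]][[depth]] <- NULL
  state$counts[k1] <- state$counts[k1] - 1L
  state$n_ops <- state$n_ops + 1L
  state
}

# Image that would result from one more distortion on patch k (no mutation).
probe_add_image <- function(state, k) {
  px <- patch_pixels(state$grid, k)
  img <- state$current
  blk <- img[px$rows, px$cols, , drop = FALSE]
  img[px$rows, px$cols, ] <- filter_apply_block(blk, state$filter, k,
                                                state$counts[k + 1L] + 1L)
  img
}

# Image that would result from undoing the top distortion on patch k.
probe_remove_image <- function(state, k) {
  px <- patch_pixels(state$grid, k)
  img <- state$current
  depth <- length(state$stacks[[k + 1L]])
  img[px$rows, px$cols, ] <- state$stacks[[k + 1L]][[depth]]
  img
}

#' Per-patch sensitivity of the ground-truth probability
#'
#' For every patch `i`, `p_add[i]` is the drop in the ground-truth class
#' probability caused by one more distortion on that patch
#' (`P_GT(x) - P_GT(x with distortion on i)`; positive = damaging to the
#' true class). For every currently distorted patch, `p_remove[i]` is the
#' rise in `P_GT` from undoing its most recent distortion
#' (`P_GT(x with top distortion on i undone) - P_GT(x)`; positive = that
#' distortion was damaging). Probes never mutate the state, and the model is
#' called exactly `n_patches + n_distorted` times (plus one if
#' `p_gt_current` is not supplied).
#'
#' @param bb a [as_blackbox()] classifier.
#' @param state a [perturbation_state()].
#' @param gt_label 0-based ground-truth label; defaults to the state's label.
#' @param p_gt_current current `P_GT`; computed with one extra query when
#'   `NULL`.
#' @return object of class `sensitivity_map` with `p_add`, `p_remove` (`NA`
#'   for undistorted patches), and `p_gt`.
#' @export
compute_sensitivity <- function(bb, state, gt_label = state$label,
                                p_gt_current = NULL) {
  np <- state$grid$n_patches
  gt1 <- as.integer(gt_label) + 1L
  if (is.null(p_gt_current)) {
    p_gt_current <- query_probs(bb, state$current)[1, gt1]
  }
  dist <- distorted_patches(state)
  probes <- vector("list", np + length(dist))
  for (k in seq_len(np) - 1L) probes[[k + 1L]] <- probe_add_image(state, k)
  for (j in seq_along(dist)) {
    probes[[np + j]] <- probe_remove_image(state, dist[j])
  }
  probs <- query_probs(bb, probes)
  p_add <- p_gt_current - probs[seq_len(np), gt1]
  p_remove <- rep(NA_real_, np)
  if (length(dist) > 0) {
    p_remove[dist + 1L] <- probs[np + seq_along(dist), gt1] - p_gt_current
  }
  structure(list(p_add = p_add, p_remove = p_remove, p_gt = p_gt_current),
            class = "sensitivity_map")
}
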