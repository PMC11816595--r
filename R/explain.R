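# Post-processing of successful episodes: greedy cleanup toward a minimal
# perturbation, the divergence saliency mask, and localization scoring
# against known ground-truth regions.

#' Greedy cleanup of a successful adversarial episode
#'
#' Iteratively attempts to undo distortions while keeping the image
#' misclassified, minimizing the L2 distance D. In each pass, distorted
#' patches are attempted in ascending remove-sensitivity order (least
#' damaging removals first); a removal is kept only if the image remains
#' misclassified, and passes repeat until no removal is kept. The L2
#' distance never increases and misclassification is preserved at every
#' kept step.
#'
#' @param bb a [as_blackbox()] classifier.
#' @param episode a successful `episode_result` from [run_episode()], or a
#'   [perturbation_state()] whose current image is misclassified.
#' @param gt_label 0-based ground-truth label; defaults to the state's.
#' @return the cleaned [perturbation_state()].
#' @export
cleanup_episode <- function(bb, episode, gt_label = NULL) {
  if (inherits(episode, "episode_result")) {
    if (!isTRUE(episode$success)) {
      data_stop("cleanup requires a successful episode (misclassified image)")
    }
    state <- episode$state
  } else if (inherits(episode, "perturbation_state")) {
    state <- episode
  } else {
    data_stop("episode must be an episode_result or perturbation_state")
  }
  gt <- gt_label %||% state$label
  pd_of <- function(img) {
    probability_dilution(query_probs(bb, img)[1, ], gt)
  }
  if (pd_of(state$current) <= 0) {
    data_stop("cleanup requires a misclassified starting image")
  }
  repeat {
    dist <- distorted_patches(state)
    if (length(dist) == 0) break
    smap <- compute_sensitivity(bb, state, gt)
    ord <- dist[order(smap$p_remove[dist + 1L])]  # ascending, stable
    kept_any <- FALSE
    for (k in ord) {
      if (state$counts[k + 1L] < 1L) next
      trial <- remove_distortion(state, k)
      if (pd_of(trial$current) > 0) {
        state <- trial
        kept_any <- TRUE
      }
    }
    if (!kept_any) break
  }
  state
}

#' Divergence saliency mask
#'
#' Per-pixel absolute difference between the adversarial and original
#' images, summed over channels and normalized by its maximum (zero-safe).
#' The mask is zero wherever the images agree, so its support is contained
#' in the union of distorted patches; it highlights the regions whose
#' perturbation drove the decision flip.
#'
#' @param original,adversarial image arrays (or [image_sample()] /
#'   [perturbation_state()]) of identical shape.
#' @param grid optional [segment_patches()] grid; when given, the 0-based
#'   indices of patches with any nonzero divergence are recorded as the mask
#'   support.
#' @param episode_id provenance string.
#' @return object of class `saliency_mask` with `values` (`H x W` in
#'   `[0,1]`, max 1 whenever any pixel differs), `support`, `provenance`.
#' @export
compute_mask <- function(original, adversarial, grid = NULL,
                         episode_id = "") {
  if (inherits(original, "image_sample")) original <- original$pixels
  if (inherits(adversarial, "perturbation_state")) {
    adversarial <- adversarial$current
  }
  original <- as_image_array(original)
  adversarial <- as_image_array(adversarial)
  if (!identical(dim(original), dim(adversarial))) {
    data_stop("original and adversarial images differ in shape")
  }
  dif <- abs(adversarial - original)
  vals <- matrix(0, dim(dif)[1], dim(dif)[2])
  for (ch in seq_len(dim(dif)[3])) vals <- vals + dif[, , ch]
  mx <- max(vals)
  if (mx > 0) vals <- vals / mx
  support <- integer(0)
  if (!is.null(grid)) {
    support <- Filter(function(k) {
      px <- patch_pixels(grid, k)
      any(vals[px$rows, px$cols] > 0)
    }, seq_len(grid$n_patches) - 1L)
  }
  structure(list(values = vals, support = as.integer(support),
                 provenance = episode_id),
            class = "saliency_mask")
}

#' Localization enrichment of a saliency mask
#'
#' The fraction of total mask mass falling inside the ground-truth
#' discriminative region, divided by the region's area fraction. A uniform
#' mask scores 1 (no better than chance); masks concentrated on the true
#' region score above 1 up to `1 / area_fraction`. An all-zero mask carries
#' no evidence and scores 0 by definition.
#'
#' @param mask a [compute_mask()] result or `H x W` matrix.
#' @param truth_region `H x W` logical matrix with at least one positive
#'   pixel.
#' @return non-negative enrichment score.
#' @export
localization_enrichment <- function(mask, truth_region) {
  vals <- if (inherits(mask, "saliency_mask")) mask$values else mask
  if (is.null(truth_region) || sum(truth_region) == 0) {
    data_stop("localization enrichment requires a non-empty truth region")
  }
  truth_region <- matrix(as.logical(truth_region), nrow(vals), ncol(vals))
  total <- sum(vals)
  if (total == 0) return(0)
  mass_frac <- sum(vals[truth_region]) / total
  area_frac <- sum(truth_region) / length(truth_region)
  mass_frac / area_frac
}
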