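# Synthetic labeled cell-like images with known discriminative regions.
#
# Real cytology datasets (HErlev, Mendeley LBC, SIPaKMeD) are class-per-folder
# trees of single-cell crops; the discriminative evidence is concentrated in
# the nucleus. The generator emulates exactly that structure at desk scale:
# each class is a "nucleus blob" whose radius and intensity distributions
# differ between classes, on a constant background with Gaussian texture
# noise, and the blob's pixel set is recorded as the ground-truth
# discriminative region so that saliency localization can be scored.

#' An image sample
#'
#' Container for one labeled image: pixels in `[0,1]`, an integer class label
#' (0-based, matching lexicographic folder order), and, for synthetic images,
#' the ground-truth discriminative-region mask.
#'
#' @param pixels numeric `H x W x C` array (or `H x W` matrix) with values in
#'   `[0,1]`.
#' @param label integer class index, `>= 0`.
#' @param truth_region optional `H x W` logical/0-1 matrix marking the
#'   discriminative region; must contain at least one and fewer than `H*W`
#'   positive pixels.
#' @param id character identifier.
#' @return an object of class `image_sample`.
#' @export
image_sample <- function(pixels, label, truth_region = NULL, id = "") {
  pixels <- as_image_array(pixels)
  if (any(pixels < 0) || any(pixels > 1)) {
    data_stop("image pixels must lie in [0, 1]")
  }
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || label < 0L) {
    data_stop("label must be a single integer >= 0")
  }
  if (!is.null(truth_region)) {
    truth_region <- matrix(as.logical(truth_region),
                           nrow = dim(pixels)[1], ncol = dim(pixels)[2])
    npos <- sum(truth_region)
    if (npos < 1L || npos >= prod(dim(pixels)[1:2])) {
      data_stop("truth_region must have >= 1 and < H*W positive pixels")
    }
  }
  structure(
    list(pixels = pixels, label = label, truth_region = truth_region,
         id = as.character(id)),
    class = "image_sample"
  )
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_sample '%s'> %dx%dx%d, label %d%s\n",
              x$id, d[1], d[2], d[3], x$label,
              if (is.null(x$truth_region)) "" else
                sprintf(", truth region %d px", sum(x$truth_region))))
  invisible(x)
}

#' Specification of a synthetic cell-image dataset
#'
#' Defines the study conditions for the generated fixture: number of classes,
#' image geometry, per-class nucleus-blob parameters, and background noise.
#' Classes must be distinguishable by construction, i.e. the per-class blob
#' parameters must differ between at least two classes.
#'
#' Defaults emulate a two-class screening problem on 16x16 grayscale crops
#' of single cells on a mid-gray background: the classes differ in nuclear
#' staining density, one hypochromatic (blob darker than background, pixel
#' level near 0.12) and one hyperchromatic (blob brighter, near 0.88), with
#' matched radius distributions so that the blob intensity is the sole
#' discriminative feature and the blob disk is exactly the ground-truth
#' discriminative region.
#'
#' @param n_classes integer `>= 2`.
#' @param n_per_class integer `>= 0` images per class.
#' @param image_size integer vector `c(H, W)`.
#' @param channels number of channels (1 = grayscale).
#' @param class_feature_params list of length `n_classes`; each element a list
#'   with `radius_mean`, `radius_sd`, `intensity_mean`, `intensity_sd`, and
#'   `center_jitter` (max offset, in pixels, of the blob center from the image
#'   center, uniform in each axis).
#' @param background constant background level in `[0,1]`.
#' @param background_noise_sd standard deviation of the Gaussian texture
#'   noise added to every pixel, `>= 0`.
#' @param seed integer RNG seed; generation is a pure function of the spec
#'   including this seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 2L,
                           n_per_class = 30L,
                           image_size = c(16L, 16L),
                           channels = 1L,
                           class_feature_params = NULL,
                           background = 0.5,
                           background_noise_sd = 0.02,
                           seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) config_stop("n_classes must be >= 2")
  if (n_per_class < 0L) config_stop("n_per_class must be >= 0")
  if (length(image_size) != 2L || any(image_size < 4L)) {
    config_stop("image_size must be c(H, W) with H, W >= 4")
  }
  if (is.null(class_feature_params)) {
    if (n_classes != 2L) {
      config_stop("class_feature_params must be supplied when n_classes != 2")
    }
    class_feature_params <- list(
      list(radius_mean = 2.0, radius_sd = 0.3,
           intensity_mean = -0.38, intensity_sd = 0.04, center_jitter = 2),
      list(radius_mean = 2.0, radius_sd = 0.3,
           intensity_mean = 0.38, intensity_sd = 0.04, center_jitter = 2)
    )
  }
  if (length(class_feature_params) != n_classes) {
    config_stop("class_feature_params must have one entry per class")
  }
  key <- vapply(class_feature_params, function(p) {
    paste(p$radius_mean, p$radius_sd, p$intensity_mean, p$intensity_sd,
          p$center_jitter %||% 0)
  }, character(1))
  if (length(unique(key)) < 2L) {
    config_stop(paste(
      "degenerate synthetic spec: class_feature_params are identical for all",
      "classes, so classes are indistinguishable by construction"))
  }
  structure(
    list(n_classes = n_classes, n_per_class = as.integer(n_per_class),
         image_size = as.integer(image_size), channels = as.integer(channels),
         class_feature_params = class_feature_params,
         background = background,
         background_noise_sd = background_noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Disk mask of |pixel - center| <= radius (Euclidean, pixel centers).
blob_mask <- function(H, W, center, radius) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

#' Generate a synthetic dataset
#'
#' Draws `n_classes * n_per_class` images. Each image is a constant
#' background plus Gaussian texture noise, with a class-specific nucleus blob
#' added inside a disk; the disk is recorded as `truth_region`. Generation is
#' a pure function of the spec (same spec, same seed, identical pixels) and
#' leaves the caller's RNG state untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return list of [image_sample()] objects, classes in label order.
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_per_class == 0L) return(list())
  H <- spec$image_size[1]; W <- spec$image_size[2]; C <- spec$channels
  with_seed(spec$seed, {
    samples <- vector("list", spec$n_classes * spec$n_per_class)
    k <- 0L
    for (cls in seq_len(spec$n_classes) - 1L) {
      p <- spec$class_feature_params[[cls + 1L]]
      jit <- p$center_jitter %||% 0
      for (i in seq_len(spec$n_per_class)) {
        center <- c((H + 1) / 2, (W + 1) / 2) +
          stats::runif(2, -jit, jit)
        radius <- max(1.0, stats::rnorm(1, p$radius_mean, p$radius_sd))
        intensity <- stats::rnorm(1, p$intensity_mean, p$intensity_sd)
        mask <- blob_mask(H, W, center, radius)
        # degenerate guard: keep at least the nearest pixel inside
        if (!any(mask)) mask[round(center[1]), round(center[2])] <- TRUE
        base <- matrix(spec$background, H, W)
        base[mask] <- base[mask] + intensity
        pix <- array(NA_real_, dim = c(H, W, C))
        for (ch in seq_len(C)) {
          noise <- if (spec$background_noise_sd > 0) {
            matrix(stats::rnorm(H * W, 0, spec$background_noise_sd), H, W)
          } else 0
          pix[, , ch] <- base + noise
        }
        k <- k + 1L
        samples[[k]] <- image_sample(
          clip01(pix), label = cls, truth_region = mask,
          id = sprintf("class%02d_img%04d", cls, i))
      }
    }
    samples
  })
}

# Run-length encode a logical matrix (column-major scan) for the JSON sidecar.
rle_encode_mask <- function(mask) {
  r <- rle(as.integer(mask))
  list(dim = dim(mask), lengths = r$lengths, values = r$values)
}

rle_decode_mask <- function(enc) {
  v <- inverse.rle(list(lengths = as.integer(enc$lengths),
                        values = as.integer(enc$values)))
  matrix(as.logical(v), nrow = enc$dim[1], ncol = enc$dim[2])
}
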