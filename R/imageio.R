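# PNG dataset I/O: class-per-folder trees (HErlev / Mendeley LBC / SIPaKMeD
# layout), heatmap export, and the JSON sidecar for synthetic datasets.

#' Write a dataset as a class-per-folder PNG tree
#'
#' Lays the samples out as `root/<class_name>/<id>.png`, the directory layout
#' used by the public single-cell cytology datasets. Class folder names are
#' `class_00`, `class_01`, ... so that lexicographic order reproduces the
#' labels. When any sample carries a `truth_region`, a JSON sidecar
#' (`root/truth.json`) records the run-length-encoded masks and, optionally,
#' the generating spec and seed.
#'
#' @param samples list of [image_sample()] objects.
#' @param root output directory (created if missing).
#' @param spec optional [synthetic_spec()] recorded in the sidecar.
#' @param force overwrite an existing non-empty directory.
#' @return `root`, invisibly.
#' @export
write_image_folder <- function(samples, root, spec = NULL, force = FALSE) {
  if (dir.exists(root) && length(list.files(root)) > 0 && !force) {
    data_stop(sprintf(
      "output directory '%s' exists and is not empty (use force = TRUE)", root))
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  for (s in samples) {
    cls_dir <- file.path(root, sprintf("class_%02d", s$label))
    dir.create(cls_dir, showWarnings = FALSE)
    path <- file.path(cls_dir, paste0(s$id, ".png"))
    pix <- s$pixels
    if (dim(pix)[3] == 1L) pix <- pix[, , 1]
    png::writePNG(pix, path)
    if (!is.null(s$truth_region)) {
      truth[[paste0(sprintf("class_%02d", s$label), "/", s$id, ".png")]] <-
        rle_encode_mask(s$truth_region)
    }
  }
  if (length(truth) > 0 || !is.null(spec)) {
    sidecar <- list(truth_regions = truth)
    if (!is.null(spec)) {
      sidecar$spec <- unclass(spec)
      sidecar$seed <- spec$seed
    }
    jsonlite::write_json(sidecar, file.path(root, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(root)
}

#' Load a class-per-folder image dataset
#'
#' Reads `root/<class_name>/*.png`. Labels are assigned by lexicographic
#' order of the class subdirectory names, starting at 0; pixel values are
#' rescaled to `[0,1]` (8-bit 255 reads as exactly 1.0). If a `truth.json`
#' sidecar written by [write_image_folder()] is present, the ground-truth
#' regions are reattached.
#'
#' @param root dataset directory.
#' @param patch_size optional patch side length `n`; when given, every image
#'   whose height or width is not divisible by `n` raises an error naming the
#'   offending file.
#' @return list of [image_sample()] objects.
#' @export
load_image_folder <- function(root, patch_size = NULL) {
  if (!dir.exists(root)) data_stop(sprintf("dataset root '%s' not found", root))
  class_dirs <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(class_dirs) == 0) {
    data_stop(sprintf("dataset root '%s' contains no class subdirectories", root))
  }
  sidecar_path <- file.path(root, "truth.json")
  truth <- NULL
  if (file.exists(sidecar_path)) {
    truth <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)$truth_regions
  }
  samples <- list()
  for (li in seq_along(class_dirs)) {
    cls_name <- class_dirs[li]
    files <- sort(list.files(file.path(root, cls_name), pattern = "\\.png$",
                             full.names = FALSE))
    for (f in files) {
      path <- file.path(root, cls_name, f)
      pix <- tryCatch(png::readPNG(path), error = function(e) {
        data_stop(sprintf("unreadable PNG '%s': %s", path, conditionMessage(e)))
      })
      if (length(dim(pix)) == 3L && dim(pix)[3] == 4L) {
        pix <- pix[, , 1:3]  # drop alpha
      }
      pix <- as_image_array(pix)
      if (!is.null(patch_size)) {
        d <- dim(pix)
        if (d[1] %% patch_size != 0 || d[2] %% patch_size != 0) {
          data_stop(sprintf(
            "image '%s' has size %dx%d, not divisible by patch size %d",
            path, d[1], d[2], patch_size))
        }
      }
      tr <- NULL
      key <- paste0(cls_name, "/", f)
      if (!is.null(truth) && key %in% names(truth)) {
        tr <- rle_decode_mask(truth[[key]])
      }
      samples[[length(samples) + 1L]] <- image_sample(
        pix, label = li - 1L, truth_region = tr,
        id = tools::file_path_sans_ext(f))
    }
  }
  samples
}

#' Write a saliency heatmap as an 8-bit grayscale PNG
#'
#' @param mask numeric `H x W` matrix with values in `[0,1]`.
#' @param path output file path.
#' @return `path`, invisibly. A round-trip read recovers the values within
#'   1/255 (8-bit quantization).
#' @export
write_heatmap <- function(mask, path) {
  if (!is.matrix(mask)) {
    if (inherits(mask, "saliency_mask")) mask <- mask$values
    else data_stop("mask must be an H x W matrix")
  }
  if (any(is.na(mask)) || any(mask < 0) || any(mask > 1)) {
    data_stop("heatmap values must lie in [0, 1]")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(mask, path)
  invisible(path)
}
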