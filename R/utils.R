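# Internal helpers shared across modules.

#' Clip numeric values to the unit interval
#'
#' Every image produced by this package lives in `[0,1]^d`; all distortion
#' operations clip through this helper.
#'
#' @param x numeric vector or array.
#' @return `x` with values below 0 set to 0 and above 1 set to 1.
#' @keywords internal
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministically fold a sequence of non-negative integers into one 32-bit
# seed (linear congruential mix, always < 2^31).
derive_seed <- function(...) {
  ids <- as.numeric(c(...))
  s <- 0
  for (v in ids) {
    s <- (s * 69069 + (abs(v) %% 2147483647)) %% 2147483647
  }
  as.integer(s)
}

# Classed conditions so the CLI can map failures to exit codes:
# config errors -> 2, data errors -> 3, anything else -> 4.
rls_stop <- function(msg, class = "rlsaliency_error", call. = FALSE) {
  stop(structure(
    class = c(class, "rlsaliency_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

config_stop <- function(msg) rls_stop(msg, class = "rlsaliency_config_error")
data_stop <- function(msg) rls_stop(msg, class = "rlsaliency_data_error")

# Coerce an image to a H x W x C array (grayscale matrices get C = 1).
as_image_array <- function(pixels) {
  if (is.matrix(pixels)) {
    array(pixels, dim = c(nrow(pixels), ncol(pixels), 1L))
  } else if (is.array(pixels) && length(dim(pixels)) == 3L) {
    pixels
  } else {
    data_stop("image pixels must be an H x W matrix or H x W x C array")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
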