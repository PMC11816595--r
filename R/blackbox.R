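# Black-box classifier interface.
#
# The RL agent never touches model parameters: it only queries class
# probabilities for images. A blackbox wraps either a backbone_model or an
# arbitrary function image -> probability vector (used for toy oracles in
# tests), and counts every image evaluated so query budgets are auditable.

#' Wrap a classifier as an instrumented black-box query
#'
#' @param model a [backbone_model()], or a function taking one `H x W x C`
#'   image array and returning a probability vector.
#' @return an object of class `blackbox` with a query counter.
#' @export
as_blackbox <- function(model) {
  if (inherits(model, "blackbox")) return(model)
  e <- new.env(parent = emptyenv())
  e$n_queries <- 0L
  if (inherits(model, "backbone_model")) {
    e$fn <- function(images) predict_proba_batch(model, images)
  } else if (is.function(model)) {
    e$fn <- function(images) {
      do.call(rbind, lapply(images, function(img) as.numeric(model(img))))
    }
  } else {
    config_stop("model must be a backbone_model or a function")
  }
  class(e) <- "blackbox"
  e
}

#' Query class probabilities from a black box
#'
#' @param bb a [as_blackbox()] object.
#' @param images one image array or a list of image arrays.
#' @return `N x n_classes` probability matrix; the query counter advances by
#'   `N` (batching is an implementation convenience, each image counts as
#'   one model call).
#' @export
query_probs <- function(bb, images) {
  if (!is.list(images)) images <- list(images)
  bb$n_queries <- bb$n_queries + length(images)
  bb$fn(images)
}

#' Number of model calls issued so far
#'
#' @param bb a [as_blackbox()] object.
#' @return integer query count.
#' @export
query_count <- function(bb) bb$n_queries
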