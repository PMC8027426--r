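# Classed conditions so callers (and the CLI) can distinguish user errors
# from degenerate inputs without string matching.

err_spec <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("sofitrend_spec_error", "sofitrend_error")))
}

err_input <- function(msg) {
  stop(errorCondition(msg, class = c("sofitrend_input_error", "sofitrend_error")))
}

err_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("sofitrend_degenerate_error", "sofitrend_error")))
}

err_format <- function(msg) {
  stop(errorCondition(msg, class = c("sofitrend_format_error", "sofitrend_error")))
}

#' Validate an image stack
#'
#' An image stack is a numeric 3D array with dimensions
#' `height x width x frames` (frames in acquisition order).
#'
#' @param stack object to validate.
#' @param min_frames minimum number of frames required.
#' @return the stack, invisibly, if valid.
#' @keywords internal
check_stack <- function(stack, min_frames = 1L) {
  if (!is.array(stack) || length(dim(stack)) != 3L || !is.numeric(stack)) {
    err_input("an image stack must be a numeric 3D array (height x width x frames)")
  }
  if (dim(stack)[3] < min_frames) {
    err_input(sprintf("stack has %d frame(s); at least %d required",
                      dim(stack)[3], min_frames))
  }
  if (anyNA(stack) || any(!is.finite(stack))) {
    err_input("stack contains non-finite values")
  }
  invisible(stack)
}

#' Unfold an image stack into a pixel-trace matrix
#'
#' Rearranges a `height x width x frames` stack into the `n x k` matrix
#' whose columns are the intensity trajectories of the `k = height * width`
#' pixels over the `n` frames. The original shape is kept as an attribute so
#' [fold_pixel_traces()] inverts the operation exactly.
#'
#' @param stack numeric 3D array (`height x width x frames`).
#' @return an `n x k` numeric matrix with attribute `origin_shape = c(height, width)`.
#' @seealso [fold_pixel_traces()]
#' @export
#' @examples
#' st <- array(1:24, dim = c(2, 3, 4))
#' Y <- as_pixel_traces(st)
#' dim(Y)                        # 4 frames x 6 pixels
#' identical(fold_pixel_traces(Y), st * 1)
as_pixel_traces <- function(stack) {
  check_stack(stack)
  d <- dim(stack)
  Y <- t(matrix(as.numeric(stack), d[1] * d[2], d[3]))
  attr(Y, "origin_shape") <- d[1:2]
  Y
}

#' Refold a pixel-trace matrix into an image stack
#'
#' @param Y `n x k` matrix as produced by [as_pixel_traces()]; if
#'   `origin_shape` is missing it must be supplied.
#' @param origin_shape integer vector `c(height, width)`.
#' @return numeric 3D array `height x width x frames`.
#' @export
fold_pixel_traces <- function(Y, origin_shape = attr(Y, "origin_shape")) {
  if (is.null(origin_shape)) {
    err_input("origin_shape is required to refold a pixel-trace matrix")
  }
  if (prod(origin_shape) != ncol(Y)) {
    err_input(sprintf("origin_shape %d x %d does not match %d pixel columns",
                      origin_shape[1], origin_shape[2], ncol(Y)))
  }
  array(as.numeric(t(Y)), dim = c(origin_shape[1], origin_shape[2], nrow(Y)))
}
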