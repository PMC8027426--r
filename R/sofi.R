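#' SOFI image object
#'
#' A second-order SOFI image lives on the 2x-refined virtual-pixel grid of
#' shape `(2*height - 1) x (2*width - 1)`. Grid positions with odd row and
#' column index (1-based) are the physical pixels and carry auto-cumulants;
#' the remaining positions are virtual pixels carrying cross-cumulants of
#' neighboring physical pixels. Values are real and may be negative
#' (cumulants of noisy data); they are never clipped.
#'
#' @param values numeric matrix on the virtual-pixel grid.
#' @param source one of `"raw"`, `"batched"`, `"trend_corrected"`,
#'   `"reference"`.
#' @param batch_size integer batch length, or `NULL`.
#' @param lambda smoothing parameter used upstream, or `NULL`.
#' @return an object of class `sofi_image`.
#' @keywords internal
new_sofi_image <- function(values, source = "raw", batch_size = NULL,
                           lambda = NULL) {
  structure(values, class = c("sofi_image", "matrix", "array"),
            order = 2L, source = source, batch_size = batch_size,
            lambda = lambda,
            cross_scheme = "symmetric-neighbor (diagonal pairs averaged)")
}

#' @export
print.sofi_image <- function(x, ...) {
  cat(sprintf("Second-order SOFI image (%s): %d x %d virtual-pixel grid\n",
              attr(x, "source"), nrow(x), ncol(x)))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x), max(x)))
  if (!is.null(attr(x, "batch_size"))) {
    cat(sprintf("  batch size: %d frames\n", attr(x, "batch_size")))
  }
  if (!is.null(attr(x, "lambda"))) {
    cat(sprintf("  Whittaker lambda: %.4g\n", attr(x, "lambda")))
  }
  invisible(x)
}

#' @rdname new_sofi_image
#' @param x,object a `sofi_image`.
#' @param ... unused.
#' @export
tidy.sofi_image <- function(x, ...) {
  g <- expand.grid(row = seq_len(nrow(x)), col = seq_len(ncol(x)))
  tibble::tibble(
    row = g$row, col = g$col,
    kind = ifelse(g$row %% 2L == 1L & g$col %% 2L == 1L, "physical", "virtual"),
    value = as.numeric(x))
}

#' @rdname new_sofi_image
#' @export
autoplot.sofi_image <- function(object, ...) {
  df <- tidy.sofi_image(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Second-order SOFI (%s)", attr(object, "source")),
                  x = NULL, y = NULL, fill = "cumulant") +
    ggplot2::theme_minimal()
}

#' Second-order auto-cumulant image
#'
#' Per pixel, the auto-cumulant at zero time lag is the variance of the
#' mean-subtracted intensity trace: `<dF(t)^2>` with `dF = F - <F>` over
#' time, normalized by the number of frames (population convention). Slowly
#' blinking emitters fluctuate; static background does not, so the
#' auto-cumulant image suppresses it.
#'
#' @param stack image stack (`height x width x frames`), at least 2 frames.
#' @return numeric `height x width` matrix.
#' @export
second_order_autocumulant <- function(stack) {
  check_stack(stack, min_frames = 2L)
  d <- sweep(stack, 1:2, rowMeans(stack, dims = 2))
  rowMeans(d * d, dims = 2)
}

#' Second-order cross-cumulant SOFI image
#'
#' Computes the full second-order SOFI image on the `(2h-1) x (2w-1)`
#' virtual-pixel grid at zero time lag, without any postprocessing
#' (no distance factor, flat-fielding or deconvolution):
#' physical positions carry the pixel's auto-cumulant (variance); a virtual
#' pixel between two horizontal or vertical neighbors carries their
#' covariance `<dF_i dF_j>`; a virtual pixel at the center of a 2x2 block
#' carries the mean of the two diagonal-pair covariances, using both
#' diagonals symmetrically.
#'
#' @param stack image stack with `height, width >= 2` and at least 2 frames.
#' @param source tag recorded on the result.
#' @param lambda optional smoothing parameter to record as provenance.
#' @return a [sofi_image][new_sofi_image] of shape `(2h-1) x (2w-1)`.
#' @export
#' @examples
#' st <- array(rnorm(4 * 4 * 100), dim = c(4, 4, 100))
#' dim(second_order_crosscumulant(st))   # 7 x 7
second_order_crosscumulant <- function(stack, source = "raw", lambda = NULL) {
  check_stack(stack, min_frames = 2L)
  h <- dim(stack)[1]; w <- dim(stack)[2]
  if (h < 2L || w < 2L) {
    err_input(sprintf("cross-cumulants need height and width >= 2 (got %d x %d)", h, w))
  }
  d <- sweep(stack, 1:2, rowMeans(stack, dims = 2))
  auto <- rowMeans(d * d, dims = 2)
  horiz <- rowMeans(d[, -w, , drop = FALSE] * d[, -1, , drop = FALSE], dims = 2)
  vert  <- rowMeans(d[-h, , , drop = FALSE] * d[-1, , , drop = FALSE], dims = 2)
  diag1 <- rowMeans(d[-h, -w, , drop = FALSE] * d[-1, -1, , drop = FALSE], dims = 2)
  diag2 <- rowMeans(d[-1, -w, , drop = FALSE] * d[-h, -1, , drop = FALSE], dims = 2)

  G <- matrix(0, 2 * h - 1, 2 * w - 1)
  odd_r <- seq(1, 2 * h - 1, by = 2); odd_c <- seq(1, 2 * w - 1, by = 2)
  evn_r <- seq(2, 2 * h - 1, by = 2); evn_c <- seq(2, 2 * w - 1, by = 2)
  G[odd_r, odd_c] <- auto
  G[odd_r, evn_c] <- horiz
  G[evn_r, odd_c] <- vert
  G[evn_r, evn_c] <- (diag1 + diag2) / 2
  new_sofi_image(G, source = source, lambda = lambda)
}

#' Batch-corrected second-order SOFI
#'
#' The batching baseline for photodestruction correction: frames are split
#' into consecutive non-overlapping batches, a SOFI image is computed per
#' batch (with per-batch mean subtraction — this is what suppresses slow
#' trends), and the per-batch images are averaged without weighting. A
#' trailing remainder shorter than `batch_size` is dropped with a warning.
#'
#' @param stack image stack.
#' @param batch_size frames per batch, `>= 2` and at most the stack length.
#' @return a [sofi_image][new_sofi_image] tagged `"batched"`.
#' @export
sofi_batched <- function(stack, batch_size) {
  check_stack(stack, min_frames = 2L)
  n <- dim(stack)[3]
  batch_size <- as.integer(batch_size)
  if (length(batch_size) != 1L || is.na(batch_size) || batch_size < 2L ||
      batch_size > n) {
    err_spec(sprintf(
      "batch_size must be an integer in [2, %d] (got %s)", n,
      paste(batch_size, collapse = ",")))
  }
  n_batches <- n %/% batch_size
  dropped <- n - n_batches * batch_size
  if (dropped > 0L) {
    warning(sprintf("dropping trailing remainder of %d frame(s) (< batch_size)",
                    dropped), call. = FALSE)
  }
  acc <- 0
  for (b in seq_len(n_batches)) {
    idx <- ((b - 1L) * batch_size + 1L):(b * batch_size)
    acc <- acc + unclass(second_order_crosscumulant(stack[, , idx, drop = FALSE]))
  }
  new_sofi_image(acc / n_batches, source = "batched", batch_size = batch_size)
}

#' Second-order SOFI pipeline with optional trend correction
#'
#' One entry point for the three analysis modes compared in this package:
#' `"none"` computes cumulants on the raw stack; `"batch"` uses the batching
#' baseline ([sofi_batched()]); `"whittaker"` removes slow trends per pixel
#' with [detrend_stack()] first and computes cumulants on the corrected
#' stack.
#'
#' @param stack image stack.
#' @param mode `"none"`, `"batch"` or `"whittaker"`.
#' @param batch_size batch length for `mode = "batch"` (default 50 frames).
#' @param lambda smoothing parameter or `"auto"` for `mode = "whittaker"`.
#' @param d difference order for `mode = "whittaker"`.
#' @param grid lambda grid for automatic selection.
#' @return a [sofi_image][new_sofi_image] tagged with its source
#'   (`"raw"`, `"batched"` or `"trend_corrected"`).
#' @export
#' @examples
#' sim <- simulate_dataset(sofi_sim_config(fov_pixels = c(8, 8), n_frames = 100,
#'                                         n_fluorophores = 500, seed = 2))
#' img <- sofi_pipeline(sim$stack, mode = "whittaker", lambda = 1000)
#' attr(img, "source")
sofi_pipeline <- function(stack, mode = c("none", "batch", "whittaker"),
                          batch_size = 50L, lambda = "auto", d = 2L,
                          grid = default_lambda_grid()) {
  mode <- match.arg(mode)
  switch(mode,
    none = second_order_crosscumulant(stack, source = "raw"),
    batch = sofi_batched(stack, batch_size),
    whittaker = {
      det <- detrend_stack(stack, lambda = lambda, d = d, grid = grid)
      second_order_crosscumulant(det$corrected, source = "trend_corrected",
                                 lambda = det$lambda)
    })
}
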