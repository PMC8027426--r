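#' Finite-difference penalty matrix
#'
#' Builds the sparse `(n - d) x n` matrix `D` of d-th order finite
#' differences: row `i` carries the signed binomial coefficients of order `d`
#' starting at column `i`. `D` is the penalty operator of Whittaker smoothing;
#' its null space (polynomials of degree `< d`) is what an infinitely stiff
#' fit converges to.
#'
#' @param n signal length (number of frames), integer `> d`.
#' @param d difference order, integer `>= 1`. Order 2 penalizes curvature and
#'   is the default throughout the package.
#' @return a sparse matrix (class `dgCMatrix`) of dimension `(n - d) x n`,
#'   directly usable by sparse solvers without densification.
#' @export
#' @examples
#' difference_matrix(7, 2)
difference_matrix <- function(n, d = 2L) {
  n <- as.integer(n)
  d <- as.integer(d)
  if (length(n) != 1L || length(d) != 1L || is.na(n) || is.na(d) || d < 1L) {
    err_spec("difference order d must be a single integer >= 1")
  }
  if (n <= d) {
    err_spec(sprintf(
      "signal length n = %d must exceed the difference order d = %d", n, d))
  }
  coefs <- (-1)^(0:d) * choose(d, 0:d)
  m <- n - d
  Matrix::sparseMatrix(
    i = rep(seq_len(m), each = d + 1L),
    j = rep(seq_len(m), each = d + 1L) + rep(0:d, m),
    x = rep(coefs, m),
    dims = c(m, n))
}

# Factor (I + lambda D'D) once; reused across all pixel columns.
whittaker_factor <- function(n, lambda, d) {
  D <- difference_matrix(n, d)
  A <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(D)
  Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda <= 0 || !is.finite(lambda)) {
    err_spec("smoothing parameter lambda must be a single finite value > 0")
  }
  lambda
}

#' Whittaker smoothing of a single trace
#'
#' Computes the penalized-least-squares fit minimizing
#' \deqn{\|y - \mu\|^2 + \lambda \|D \mu\|^2,}
#' where `D` takes d-th order finite differences. The unique minimizer
#' \eqn{\hat\mu = (I + \lambda D'D)^{-1} y} is obtained by a sparse Cholesky
#' factorization of the banded system (O(n) time and memory), never by dense
#' inversion.
#'
#' @param y numeric vector of length `n > d`, all finite.
#' @param lambda penalty weight, `> 0`. Larger values give smoother fits; as
#'   `lambda -> 0` the fit reproduces `y`, as `lambda -> Inf` (with `d = 2`)
#'   it converges to the least-squares straight line.
#' @param d difference order (default 2).
#' @return numeric vector of length `n`, the smooth fit.
#' @seealso [smooth_matrix()] for all pixels of a stack at once,
#'   [select_lambda_vcurve()] for automatic choice of `lambda`.
#' @export
#' @examples
#' y <- sin(seq(0, 2 * pi, length.out = 100)) + rnorm(100, sd = 0.2)
#' mu <- smooth_trace(y, lambda = 100)
smooth_trace <- function(y, lambda, d = 2L) {
  if (!is.numeric(y)) err_input("y must be numeric")
  if (anyNA(y) || any(!is.finite(y))) {
    err_input("y contains non-finite values; Whittaker smoothing requires finite input")
  }
  check_lambda(lambda)
  ch <- whittaker_factor(length(y), lambda, d)
  as.numeric(Matrix::solve(ch, y))
}

#' Whittaker smoothing of all pixel traces of an image stack
#'
#' Fits every column of a pixel-trace matrix independently with the same
#' penalty weight. The system matrix `(I + lambda D'D)` depends only on the
#' frame count, so it is factored once and the factor is reused for all `k`
#' pixel columns.
#'
#' @param Y `n x k` numeric matrix (frames by pixels), e.g. from
#'   [as_pixel_traces()].
#' @inheritParams smooth_trace
#' @return an object of class `whittaker_trend`: a list with elements
#'   `fits` (`n x k` matrix of smooth fits), `lambda`, `d`, and
#'   `origin_shape` (carried over from `Y` when present).
#' @export
smooth_matrix <- function(Y, lambda, d = 2L) {
  Y <- as.matrix(Y)
  if (anyNA(Y) || any(!is.finite(Y))) {
    err_input("Y contains non-finite values")
  }
  check_lambda(lambda)
  if (nrow(Y) <= d) {
    err_spec(sprintf("Y has %d frames; need more than d = %d", nrow(Y), d))
  }
  ch <- whittaker_factor(nrow(Y), lambda, d)
  fits <- as.matrix(Matrix::solve(ch, Y))
  dimnames(fits) <- dimnames(Y)
  structure(
    list(fits = fits, lambda = lambda, d = as.integer(d),
         origin_shape = attr(Y, "origin_shape")),
    class = "whittaker_trend")
}

#' @export
print.whittaker_trend <- function(x, ...) {
  cat(sprintf("Whittaker trend model: %d frames x %d pixels, lambda = %g, d = %d\n",
              nrow(x$fits), ncol(x$fits), x$lambda, x$d))
  invisible(x)
}

#' @rdname smooth_matrix
#' @param x a `whittaker_trend` object.
#' @param ... unused.
#' @export
glance.whittaker_trend <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, d = x$d,
                 n_frames = nrow(x$fits), n_pixels = ncol(x$fits))
}

#' Default smoothing-parameter grid for V-curve selection
#'
#' Log-spaced grid from `1e-2` to `1e8`, 10 points per decade. The span
#' covers near-interpolating fits (small lambda) up to the straight-line
#' limit (large lambda) for the frame counts typical of SOFI acquisitions
#' (hundreds to thousands of frames).
#'
#' @return increasing numeric vector of lambda values.
#' @export
default_lambda_grid <- function() {
  10^seq(-2, 8, by = 0.1)
}

#' Automatic smoothing-parameter selection by the V-curve
#'
#' For each candidate `lambda` the whole image is smoothed and two aggregate
#' norms are recorded: the fit term `f = log10(sum over pixels of ||y - mu||^2)`
#' and the penalty term `p = log10(sum over pixels of ||D mu||^2)`. The
#' V-curve is the speed of travel along the parametric curve `(f, p)`:
#' `v_k = sqrt((f_{k+1} - f_k)^2 + (p_{k+1} - p_k)^2)` for consecutive grid
#' points. The selected `lambda` is the geometric mean of the grid interval
#' where `v` is minimal — the flattest point of the trade-off curve, which
#' needs no noise estimate and no user tuning.
#'
#' One global `lambda` is chosen for the image in its entirety (norms are
#' summed over pixel columns). A per-pixel mode is available via
#' `per_pixel = TRUE`, returning one `lambda` per column; the global mode is
#' the default.
#'
#' @param Y `n x k` pixel-trace matrix (or an image stack, which is unfolded).
#' @param grid strictly increasing vector of at least 3 candidate lambdas,
#'   all `> 0`; see [default_lambda_grid()].
#' @param d difference order (default 2).
#' @param max_pixels for large images, the number of pixel columns used for
#'   selection; if `k > max_pixels` a uniform random subsample of columns is
#'   drawn (using the current RNG stream). Default 4096 (all pixels for
#'   fields up to 64 x 64).
#' @param per_pixel if `TRUE`, run the V-curve independently per pixel column
#'   and return a vector of lambdas (diagnostics then cover the global curve
#'   only).
#' @return an object of class `vcurve_selection`: list with `lambda` (the
#'   selected value, or vector if `per_pixel`), `index` (grid interval
#'   chosen), and `diagnostics`, a tibble with columns `lambda`, `log10_fit`,
#'   `log10_penalty` and `v` (the V-value of the interval starting at that
#'   row; `NA` for the last row). Use [tidy()] to extract the tibble and
#'   [autoplot()] to plot the curve.
#' @export
select_lambda_vcurve <- function(Y, grid = default_lambda_grid(), d = 2L,
                                 max_pixels = 4096L, per_pixel = FALSE) {
  if (is.array(Y) && length(dim(Y)) == 3L) Y <- as_pixel_traces(Y)
  Y <- as.matrix(Y)
  if (!is.numeric(grid) || length(grid) < 3L) {
    err_spec("lambda grid must contain at least 3 values")
  }
  if (any(grid <= 0) || any(diff(grid) <= 0)) {
    err_spec("lambda grid must be strictly increasing and positive")
  }
  if (nrow(Y) <= d) {
    err_spec(sprintf("Y has %d frames; need more than d = %d", nrow(Y), d))
  }
  if (ncol(Y) > max_pixels) {
    Y <- Y[, sort(sample.int(ncol(Y), max_pixels)), drop = FALSE]
  }
  D <- difference_matrix(nrow(Y), d)
  if (sum(as.matrix(D %*% Y)^2) == 0) {
    err_degenerate(paste(
      "every pixel trace is already in the null space of the difference",
      "penalty (e.g. constant or exactly linear); smoothing is unnecessary",
      "and the V-curve is undefined"))
  }

  norms <- vapply(grid, function(lambda) {
    M <- as.matrix(Matrix::solve(whittaker_factor(nrow(Y), lambda, d), Y))
    c(fit = sum((Y - M)^2), pen = sum(as.matrix(D %*% M)^2))
  }, numeric(2))
  f <- log10(norms["fit", ])
  p <- log10(norms["pen", ])
  v <- sqrt(diff(f)^2 + diff(p)^2)
  idx <- which.min(v)
  lambda_sel <- sqrt(grid[idx] * grid[idx + 1L])
  if (idx == 1L || idx == length(v)) {
    warning("V-curve minimum lies at the edge of the lambda grid; ",
            "consider widening the grid", call. = FALSE)
  }

  if (per_pixel) {
    lambda_sel <- apply(Y, 2, function(y) {
      fits <- vapply(grid, function(lambda) {
        mu <- smooth_trace(y, lambda, d)
        c(sum((y - mu)^2), sum(as.numeric(D %*% mu)^2))
      }, numeric(2))
      vv <- sqrt(diff(log10(fits[1, ]))^2 + diff(log10(fits[2, ]))^2)
      i <- which.min(vv)
      sqrt(grid[i] * grid[i + 1L])
    })
  }

  structure(
    list(lambda = lambda_sel, index = idx,
         diagnostics = tibble::tibble(
           lambda = grid, log10_fit = f, log10_penalty = p,
           v = c(v, NA_real_)),
         d = as.integer(d), per_pixel = per_pixel),
    class = "vcurve_selection")
}

#' @export
print.vcurve_selection <- function(x, ...) {
  if (x$per_pixel) {
    cat(sprintf("V-curve selection (per pixel): median lambda = %.4g over %d pixels\n",
                stats::median(x$lambda), length(x$lambda)))
  } else {
    cat(sprintf("V-curve selection: lambda = %.4g (grid interval %d, d = %d)\n",
                x$lambda, x$index, x$d))
  }
  invisible(x)
}

#' @rdname select_lambda_vcurve
#' @param x a `vcurve_selection` object.
#' @param ... unused.
#' @export
tidy.vcurve_selection <- function(x, ...) x$diagnostics

#' @rdname select_lambda_vcurve
#' @export
glance.vcurve_selection <- function(x, ...) {
  tibble::tibble(lambda = if (x$per_pixel) stats::median(x$lambda) else x$lambda,
                 per_pixel = x$per_pixel, d = x$d,
                 grid_points = nrow(x$diagnostics))
}

#' @rdname select_lambda_vcurve
#' @param object a `vcurve_selection` object.
#' @export
autoplot.vcurve_selection <- function(object, ...) {
  dg <- object$diagnostics
  mid <- dg[-nrow(dg), ]
  mid$lambda_mid <- sqrt(mid$lambda * dg$lambda[-1])
  lam <- if (object$per_pixel) stats::median(object$lambda) else object$lambda
  ggplot2::ggplot(mid, ggplot2::aes(x = .data$lambda_mid, y = .data$v)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = lam, linetype = "dashed", colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "V-curve value",
                  title = sprintf("V-curve: selected lambda = %.3g", lam)) +
    ggplot2::theme_minimal()
}

#' Remove slow intensity trends from an image stack
#'
#' Fits every pixel's intensity trajectory by Whittaker smoothing and
#' subtracts the fit, leaving only the fast fluorescence dynamics (the
#' blinking signal SOFI relies on). Photodestruction, illumination drift and
#' other slow trends end up in the fitted component. The corrected stack may
#' — and for mean-subtracted data must — contain negative values; they are
#' never clipped.
#'
#' @param stack image stack (`height x width x frames`).
#' @param lambda penalty weight, or `"auto"` (default) to select it with the
#'   V-curve procedure on the whole image.
#' @param d difference order (default 2).
#' @param grid candidate grid for automatic selection.
#' @param max_pixels subsampling bound passed to [select_lambda_vcurve()].
#' @return object of class `sofi_detrend`: list with `corrected` (stack of
#'   `Y - M` refolded to the input shape), `trend` (a `whittaker_trend`),
#'   `lambda` (the value used) and `vcurve` (the `vcurve_selection`, or
#'   `NULL` when `lambda` was given numerically).
#' @export
#' @examples
#' st <- simulate_dataset(sofi_sim_config(fov_pixels = c(8, 8), n_frames = 80,
#'                                        n_fluorophores = 200, seed = 1))$stack
#' det <- detrend_stack(st, lambda = 100)
#' range(det$corrected)
detrend_stack <- function(stack, lambda = "auto", d = 2L,
                          grid = default_lambda_grid(), max_pixels = 4096L) {
  check_stack(stack, min_frames = d + 1L)
  Y <- as_pixel_traces(stack)
  vc <- NULL
  if (identical(lambda, "auto")) {
    vc <- select_lambda_vcurve(Y, grid = grid, d = d, max_pixels = max_pixels)
    lambda <- vc$lambda
  }
  trend <- smooth_matrix(Y, lambda, d)
  corrected <- fold_pixel_traces(Y - trend$fits, attr(Y, "origin_shape"))
  structure(
    list(corrected = corrected, trend = trend, lambda = lambda, vcurve = vc),
    class = "sofi_detrend")
}

#' @export
print.sofi_detrend <- function(x, ...) {
  d <- dim(x$corrected)
  cat(sprintf("Trend-corrected stack: %d x %d pixels, %d frames (lambda = %.4g)\n",
              d[1], d[2], d[3], x$lambda))
  invisible(x)
}
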