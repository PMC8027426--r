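test_that("difference matrix carries signed binomial coefficients", {
  D7 <- as.matrix(difference_matrix(7, 2))
  expect_identical(dim(D7), c(5L, 7L))
  expected <- rbind(c(1, -2, 1, 0, 0, 0, 0),
                    c(0, 1, -2, 1, 0, 0, 0),
                    c(0, 0, 1, -2, 1, 0, 0),
                    c(0, 0, 0, 1, -2, 1, 0),
                    c(0, 0, 0, 0, 1, -2, 1))
  expect_equal(D7, expected, ignore_attr = TRUE)

  D31 <- as.matrix(difference_matrix(3, 1))
  expect_equal(D31, rbind(c(1, -1, 0), c(0, 1, -1)), ignore_attr = TRUE)

  # higher order agrees with repeated base::diff of an identity matrix
  # (up to the overall sign for odd orders; the penalty D'D is identical)
  for (d in 1:4) {
    I10 <- diag(10)
    for (i in seq_len(d)) I10 <- diff(I10)
    expect_equal(as.matrix(difference_matrix(10, d)), (-1)^d * I10,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate difference specifications are rejected with both values named", {
  expect_error(difference_matrix(2, 2), class = "sofitrend_spec_error")
  expect_error(difference_matrix(2, 2), "n = 2.*d = 2")
  expect_error(difference_matrix(5, 0), class = "sofitrend_spec_error")
})

test_that("sparse smoother equals the dense normal-equations oracle", {
  set.seed(42)
  for (n in c(10L, 20L, 50L)) {
    for (lambda in c(0.5, 10, 1e4)) {
      y <- rnorm(n)
      expect_equal(smooth_trace(y, lambda),
                   dense_whittaker_oracle(y, lambda),
                   tolerance = 1e-8)
    }
  }
})

test_that("penalty-free and null-space limits are exact fixed points", {
  set.seed(7)
  y <- rnorm(40)
  # vanishing penalty: the fit reproduces the data
  expect_equal(smooth_trace(y, 1e-12), y, tolerance = 1e-8)
  # a linear signal is in the null space of the order-2 penalty
  ylin <- 2 * seq_len(40) + 1
  for (lambda in c(1, 1e4, 1e8)) {
    expect_equal(smooth_trace(ylin, lambda), ylin, tolerance = 1e-6)
  }
  # infinitely stiff order-2 fit converges to the least-squares line
  t <- seq_len(60)
  y2 <- 0.5 * t + rnorm(60)
  line <- unname(fitted(lm(y2 ~ t)))
  mu <- smooth_trace(y2, 1e12)
  expect_lt(max(abs(mu - line)) / max(abs(line)), 1e-4)
})

test_that("the smoother is a linear operator", {
  set.seed(11)
  y1 <- rnorm(30); y2 <- rnorm(30)
  a <- 2.5; b <- -1.25
  expect_equal(smooth_trace(a * y1 + b * y2, 100),
               a * smooth_trace(y1, 100) + b * smooth_trace(y2, 100),
               tolerance = 1e-10)
})

test_that("non-finite input is refused rather than propagated", {
  expect_error(smooth_trace(c(1, NA, 3, 4), 1), class = "sofitrend_input_error")
  expect_error(smooth_trace(c(1, Inf, 3, 4), 1), class = "sofitrend_input_error")
  expect_error(smooth_trace(1:10, -1), class = "sofitrend_spec_error")
  expect_error(smooth_trace(1:10, 0), class = "sofitrend_spec_error")
})

test_that("matrix smoothing equals per-column smoothing", {
  set.seed(13)
  Y <- matrix(rnorm(35 * 16), 35, 16)
  tr <- smooth_matrix(Y, 100)
  expect_s3_class(tr, "whittaker_trend")
  expect_identical(dim(tr$fits), dim(Y))
  for (j in seq_len(ncol(Y))) {
    expect_equal(tr$fits[, j], smooth_trace(Y[, j], 100), tolerance = 1e-10)
  }
  # single column is just the trace smoother
  tr1 <- smooth_matrix(Y[, 1, drop = FALSE], 100)
  expect_equal(as.numeric(tr1$fits), smooth_trace(Y[, 1], 100))
  # constant columns are reproduced exactly (null space for any d >= 1)
  Yc <- matrix(rep(c(3, -2, 7), each = 20), 20, 3)
  expect_equal(smooth_matrix(Yc, 1e5)$fits, Yc, tolerance = 1e-9,
               ignore_attr = TRUE)
  g <- glance(tr)
  expect_equal(g$n_pixels, 16L)
  expect_equal(g$lambda, 100)
})

test_that("residuals sum to zero for every pixel and every lambda", {
  set.seed(3)
  Y <- matrix(rnorm(200 * 25, mean = 50), 200, 25)
  for (lambda in c(1, 1e3, 1e6)) {
    tr <- smooth_matrix(Y, lambda)
    resid_sums <- colSums(Y - tr$fits)
    expect_lt(max(abs(resid_sums) / colSums(Y)), 1e-6)
  }
})

test_that("aggregate fit norm grows and penalty norm shrinks with lambda", {
  set.seed(19)
  Y <- matrix(rnorm(150 * 9), 150, 9)
  grid <- 10^seq(-2, 8, by = 0.5)
  D <- as.matrix(difference_matrix(150, 2))
  f <- p <- numeric(length(grid))
  for (i in seq_along(grid)) {
    M <- smooth_matrix(Y, grid[i])$fits
    f[i] <- sum((Y - M)^2)
    p[i] <- sum((D %*% M)^2)
  }
  expect_true(all(diff(f) >= -1e-9 * max(f)))
  expect_true(all(diff(p) <= 1e-9 * max(p)))
})

test_that("V-curve selection matches a brute-force recomputation over the grid", {
  set.seed(23)
  n <- 120
  Y <- matrix(200 * exp(-seq_len(n) / 40), n, 6) + matrix(rnorm(n * 6), n, 6)
  grid <- c(1, 100, 1e4)
  # a 3-point grid has only two intervals, so the minimum is necessarily at
  # an edge and the widen-the-grid warning must fire
  expect_warning(sel <- select_lambda_vcurve(Y, grid = grid), "edge")

  # independent brute force: dense solves, explicit norms
  f <- p <- numeric(3)
  D <- diag(n); D <- diff(diff(D))
  for (i in 1:3) {
    M <- apply(Y, 2, function(y) dense_whittaker_oracle(y, grid[i]))
    f[i] <- log10(sum((Y - M)^2))
    p[i] <- log10(sum((D %*% M)^2))
  }
  v <- sqrt(diff(f)^2 + diff(p)^2)
  i <- which.min(v)
  expect_equal(sel$lambda, sqrt(grid[i] * grid[i + 1]), tolerance = 1e-10)
  expect_equal(sel$diagnostics$log10_fit, f, tolerance = 1e-7)
  expect_equal(sel$diagnostics$log10_penalty, p, tolerance = 1e-7)
  expect_equal(sel$diagnostics$v[1:2], v, tolerance = 1e-7)
  expect_true(is.na(sel$diagnostics$v[3]))
})

test_that("V-curve on white noise selects an interior grid point", {
  set.seed(29)
  Y <- matrix(rnorm(300 * 8), 300, 8)
  sel <- select_lambda_vcurve(Y)
  grid <- default_lambda_grid()
  expect_gt(sel$index, 1L)
  expect_lt(sel$index, length(grid) - 1L)
  expect_gt(sel$lambda, grid[1])
  expect_lt(sel$lambda, grid[length(grid)])
})

test_that("V-curve rejects degenerate input and bad grids", {
  Ylin <- outer(1:50, c(1, 2, -3))          # every column exactly linear
  expect_error(select_lambda_vcurve(Ylin), class = "sofitrend_degenerate_error")
  expect_error(select_lambda_vcurve(Ylin), "smoothing is unnecessary")
  Y <- matrix(rnorm(100), 50, 2)
  expect_error(select_lambda_vcurve(Y, grid = c(1, 10)),
               class = "sofitrend_spec_error")
  expect_error(select_lambda_vcurve(Y, grid = c(10, 1, 100)),
               class = "sofitrend_spec_error")
  expect_error(select_lambda_vcurve(Y, grid = c(-1, 1, 10)),
               class = "sofitrend_spec_error")
})

test_that("per-pixel V-curve mode returns one lambda per column", {
  set.seed(31)
  Y <- cbind(100 * exp(-(1:150) / 30) + rnorm(150), rnorm(150))
  sel <- select_lambda_vcurve(Y, grid = 10^seq(0, 8, by = 1), per_pixel = TRUE)
  expect_length(sel$lambda, 2L)
  expect_true(all(sel$lambda > 0))
})

test_that("unfold/refold of a stack is exactly invertible", {
  set.seed(37)
  st <- array(rnorm(5 * 4 * 12), dim = c(5, 4, 12))
  Y <- as_pixel_traces(st)
  expect_identical(dim(Y), c(12L, 20L))
  expect_equal(fold_pixel_traces(Y), st)
  # trace of pixel (i, j) is the right column
  expect_equal(Y[, 2 + (3 - 1) * 5], st[2, 3, ])
})

test_that("detrending removes a known bleaching envelope", {
  st <- bleached_fixture_stack()
  det <- detrend_stack(st, lambda = "auto")
  expect_s3_class(det, "sofi_detrend")
  expect_s3_class(det$vcurve, "vcurve_selection")
  # per-pixel time-sums of the corrected stack vanish
  sums <- apply(det$corrected, c(1, 2), sum)
  totals <- apply(st, c(1, 2), sum)
  expect_lt(max(abs(sums) / abs(totals)), 1e-6)
  # the trend (decay envelope) carries almost all the variance
  var_raw <- apply(st, c(1, 2), var)
  var_cor <- apply(det$corrected, c(1, 2), var)
  expect_lt(max(var_cor / var_raw), 0.05)
})

test_that("a constant stack detrends to exactly zero", {
  st <- array(7, dim = c(3, 3, 30))
  det <- detrend_stack(st, lambda = 10)
  expect_equal(max(abs(det$corrected)), 0, tolerance = 1e-9)
})

test_that("corrected stacks keep their negative values", {
  st <- bleached_fixture_stack(n = 100)
  det <- detrend_stack(st, lambda = 1e4)
  expect_lt(min(det$corrected), 0)
})
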