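# Shared fixtures and independent oracles used across the suite.

# Dense-matrix Whittaker oracle: explicit solve of (I + lambda D'D) mu = y,
# with D built by repeated base::diff on an identity matrix - a construction
# independent of the package's sparse path.
dense_whittaker_oracle <- function(y, lambda, d = 2L) {
  n <- length(y)
  D <- diag(n)
  for (i in seq_len(d)) D <- diff(D)
  solve(diag(n) + lambda * t(D) %*% D, y)
}

# A small blinking simulation used by several tests.
small_sim_config <- function(..., seed = 101L) {
  sofi_sim_config(fov_pixels = c(8L, 8L), n_frames = 200L,
                  n_fluorophores = 500L, n_lines = 3L, seed = seed, ...)
}

# Stack with a known multiplicative bleaching trend plus i.i.d. noise.
bleached_fixture_stack <- function(h = 6L, w = 6L, n = 250L, seed = 5L) {
  set.seed(seed)
  base_img <- matrix(runif(h * w, 50, 150), h, w)
  envelope <- exp(-(seq_len(n) - 1) / (n / 3))
  stack <- array(0, dim = c(h, w, n))
  for (t in seq_len(n)) {
    stack[, , t] <- base_img * envelope[t] + rnorm(h * w, sd = 1)
  }
  stack
}

# Manually constructed emitter set (bypasses random placement) so photon
# budgets can be checked exactly.
manual_emitter_set <- function(x_nm, y_nm, on_fraction) {
  structure(
    list(positions = tibble::tibble(x_nm = x_nm, y_nm = y_nm,
                                    line = rep(1L, length(x_nm))),
         bleach_time_s = rep(Inf, length(x_nm)),
         on_fraction = on_fraction),
    class = "emitter_set")
}
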