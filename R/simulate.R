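#' Simulation configuration for synthetic SOFI datasets
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' reproduce the standard simulated acquisition used throughout: a
#' 32 x 32 pixel field (100 nm pixels) imaged for 500 frames at 10 ms
#' exposure, containing 20,000 blinking fluorophores placed on 10 randomly
#' oriented intersecting lines. Each fluorophore is an independent two-state
#' continuous-time Markov chain with mean dwell times `tau_on = 10 ms` and
#' `tau_off = 100 ms` (stationary on-time ratio 10/110, i.e. 9%), emitting
#' 30 photons per ms while on, imaged through a Gaussian PSF set by
#' NA = 1.4 and emission wavelength 520 nm, and irreversibly photobleached
#' after an exponentially distributed survival time `tau_bleach_s`.
#' Detection adds a Poisson background of 10 photons per pixel per frame,
#' shot noise, an EMCCD gain register (EM gain 50) and a camera offset of
#' 1000 counts.
#'
#' @param fov_pixels integer c(height, width) of the field of view.
#' @param n_frames number of frames.
#' @param pixel_size_nm pixel pitch in nm.
#' @param n_fluorophores total number of emitters.
#' @param n_lines number of random lines carrying the emitters.
#' @param tau_on_ms mean on-state dwell time (ms).
#' @param tau_off_ms mean off-state dwell time (ms).
#' @param tau_bleach_s mean photobleaching survival time (s); `Inf` disables
#'   photodestruction.
#' @param photon_rate_per_ms emitted photons per ms while on.
#' @param numerical_aperture objective NA.
#' @param emission_wavelength_nm emission wavelength (nm). This is the
#'   optical wavelength, unrelated to the smoothing parameter.
#' @param exposure_ms exposure time per frame (ms); frames are contiguous.
#' @param camera_offset camera baseline in counts.
#' @param em_gain mean electron-multiplication gain (counts per photon).
#' @param em_gain_model `"gamma"` for the stochastic EMCCD gain-register
#'   model (output ~ Gamma(shape = photons, scale = em_gain)), or
#'   `"simple"` for deterministic multiplication (useful in analytic tests).
#' @param background_photons mean Poisson background per pixel per frame.
#' @param read_noise_sd additive Gaussian read noise (counts); default 0.
#' @param psf_sigma_nm Gaussian PSF standard deviation in nm; by default
#'   derived from the diffraction limit as
#'   `FWHM = wavelength / (2 NA)`, `sigma = FWHM / (2 sqrt(2 log 2))`
#'   (about 78.9 nm at the defaults).
#' @param seed RNG seed used by [simulate_dataset()]; `NULL` leaves the
#'   current RNG state untouched.
#' @return a validated list of class `sofi_sim_config`.
#' @export
sofi_sim_config <- function(fov_pixels = c(32L, 32L),
                            n_frames = 500L,
                            pixel_size_nm = 100,
                            n_fluorophores = 20000L,
                            n_lines = 10L,
                            tau_on_ms = 10,
                            tau_off_ms = 100,
                            tau_bleach_s = 1.1,
                            photon_rate_per_ms = 30,
                            numerical_aperture = 1.4,
                            emission_wavelength_nm = 520,
                            exposure_ms = 10,
                            camera_offset = 1000,
                            em_gain = 50,
                            em_gain_model = c("gamma", "simple"),
                            background_photons = 10,
                            read_noise_sd = 0,
                            psf_sigma_nm = NULL,
                            seed = NULL) {
  cfg <- list(
    fov_pixels = as.integer(rep_len(fov_pixels, 2L)),
    n_frames = as.integer(n_frames),
    pixel_size_nm = pixel_size_nm,
    n_fluorophores = as.integer(n_fluorophores),
    n_lines = as.integer(n_lines),
    tau_on_ms = tau_on_ms, tau_off_ms = tau_off_ms,
    tau_bleach_s = tau_bleach_s,
    photon_rate_per_ms = photon_rate_per_ms,
    numerical_aperture = numerical_aperture,
    emission_wavelength_nm = emission_wavelength_nm,
    exposure_ms = exposure_ms,
    camera_offset = camera_offset,
    em_gain = em_gain,
    em_gain_model = match.arg(em_gain_model),
    background_photons = background_photons,
    read_noise_sd = read_noise_sd,
    psf_sigma_nm = psf_sigma_nm,
    seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  pos <- c("pixel_size_nm", "tau_on_ms", "tau_off_ms", "tau_bleach_s",
           "photon_rate_per_ms", "numerical_aperture",
           "emission_wavelength_nm", "exposure_ms", "em_gain")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      err_spec(sprintf("simulation parameter '%s' must be a single value > 0", f))
    }
  }
  if (any(cfg$fov_pixels < 1L) || cfg$n_frames < 1L || cfg$n_fluorophores < 0L ||
      cfg$n_lines < 1L) {
    err_spec("fov_pixels, n_frames and n_lines must be positive integers; n_fluorophores >= 0")
  }
  if (cfg$background_photons < 0 || cfg$read_noise_sd < 0 || cfg$camera_offset < 0) {
    err_spec("background_photons, read_noise_sd and camera_offset must be >= 0")
  }
  if (is.null(cfg$psf_sigma_nm)) {
    fwhm <- cfg$emission_wavelength_nm / (2 * cfg$numerical_aperture)
    cfg$psf_sigma_nm <- fwhm / (2 * sqrt(2 * log(2)))
  }
  if (cfg$psf_sigma_nm <= 0) err_spec("psf_sigma_nm must be > 0")
  structure(cfg, class = "sofi_sim_config")
}

#' @export
print.sofi_sim_config <- function(x, ...) {
  cat(sprintf(
    "SOFI simulation config: %d x %d px (%g nm), %d frames @ %g ms\n",
    x$fov_pixels[1], x$fov_pixels[2], x$pixel_size_nm, x$n_frames, x$exposure_ms))
  cat(sprintf(
    "  %d emitters on %d lines; tau_on %g ms, tau_off %g ms, tau_bl %g s\n",
    x$n_fluorophores, x$n_lines, x$tau_on_ms, x$tau_off_ms, x$tau_bleach_s))
  cat(sprintf(
    "  %g photons/ms, PSF sigma %.1f nm; offset %g, EM gain %g (%s), bg %g\n",
    x$photon_rate_per_ms, x$psf_sigma_nm, x$camera_offset, x$em_gain,
    x$em_gain_model, x$background_photons))
  invisible(x)
}

#' Place emitters on random lines
#'
#' Draws `n_lines` lines, each with a uniform random orientation in
#' `[0, pi)` and a uniform random anchor point inside the field of view, and
#' distributes the emitters as evenly as possible across lines (counts
#' differ by at most one), uniformly along each line's chord through the
#' field of view.
#'
#' @param config a [sofi_sim_config()].
#' @return object of class `emitter_set`: list with `positions` (tibble
#'   with columns `x_nm`, `y_nm`, `line`), and empty slots `bleach_time_s`
#'   and `on_fraction` to be filled by [simulate_timecourses()].
#' @export
generate_emitters <- function(config) {
  stopifnot(inherits(config, "sofi_sim_config"))
  h_nm <- config$fov_pixels[1] * config$pixel_size_nm
  w_nm <- config$fov_pixels[2] * config$pixel_size_nm
  N <- config$n_fluorophores
  L <- config$n_lines

  counts <- rep(N %/% L, L)
  if (N %% L > 0) counts[seq_len(N %% L)] <- counts[seq_len(N %% L)] + 1L

  xs <- numeric(0); ys <- numeric(0); line_id <- integer(0)
  for (l in seq_len(L)) {
    ang <- runif(1, 0, pi)
    ax <- runif(1, 0, w_nm); ay <- runif(1, 0, h_nm)
    dx <- cos(ang); dy <- sin(ang)
    # chord of the line through (ax, ay): clip parameter t to the FOV box
    tr <- c(-Inf, Inf)
    if (abs(dx) > 1e-12) {
      tx <- sort(c((0 - ax) / dx, (w_nm - ax) / dx))
      tr <- c(max(tr[1], tx[1]), min(tr[2], tx[2]))
    }
    if (abs(dy) > 1e-12) {
      ty <- sort(c((0 - ay) / dy, (h_nm - ay) / dy))
      tr <- c(max(tr[1], ty[1]), min(tr[2], ty[2]))
    }
    t <- runif(counts[l], tr[1], tr[2])
    px <- pmin(pmax(ax + t * dx, 0), w_nm * (1 - 1e-12))
    py <- pmin(pmax(ay + t * dy, 0), h_nm * (1 - 1e-12))
    xs <- c(xs, px); ys <- c(ys, py)
    line_id <- c(line_id, rep(l, counts[l]))
  }
  structure(
    list(positions = tibble::tibble(x_nm = xs, y_nm = ys, line = line_id),
         bleach_time_s = NULL, on_fraction = NULL),
    class = "emitter_set")
}

#' @export
print.emitter_set <- function(x, ...) {
  cat(sprintf("Emitter set: %d fluorophores on %d line(s)%s\n",
              nrow(x$positions), length(unique(x$positions$line)),
              if (is.null(x$on_fraction)) "" else
                sprintf("; timecourses for %d frames", ncol(x$on_fraction))))
  invisible(x)
}

#' @rdname generate_emitters
#' @param x an `emitter_set`.
#' @param ... unused.
#' @export
tidy.emitter_set <- function(x, ...) {
  out <- x$positions
  if (!is.null(x$bleach_time_s)) out$bleach_time_s <- x$bleach_time_s
  out
}

#' Simulate blinking and photodestruction timecourses
#'
#' Each emitter is an independent two-state continuous-time Markov chain:
#' dwell times in the on and off state are exponential with means
#' `tau_on_ms` and `tau_off_ms`, the initial state is drawn from the
#' stationary distribution (on with probability
#' `tau_on / (tau_on + tau_off)`), and emission stops irreversibly at a
#' photobleaching time drawn from Exponential(mean `tau_bleach_s`). The
#' simulation is event-driven (exact event times, no sub-frame
#' discretization); the per-frame `on_fraction` is the exact fraction of
#' each exposure window spent in the on state before bleaching.
#'
#' @param emitters an `emitter_set` from [generate_emitters()].
#' @param config a [sofi_sim_config()].
#' @return the `emitter_set` with `bleach_time_s` (length-N vector) and
#'   `on_fraction` (N x n_frames matrix, values in `[0, 1]`) filled in.
#' @export
simulate_timecourses <- function(emitters, config) {
  stopifnot(inherits(emitters, "emitter_set"), inherits(config, "sofi_sim_config"))
  N <- nrow(emitters$positions)
  n_frames <- config$n_frames
  dt <- config$exposure_ms / 1000
  total <- n_frames * dt
  tau_on <- config$tau_on_ms / 1000
  tau_off <- config$tau_off_ms / 1000

  bleach <- if (is.finite(config$tau_bleach_s)) {
    rexp(N, rate = 1 / config$tau_bleach_s)
  } else {
    rep(Inf, N)
  }
  T_end <- pmin(bleach, total)

  onmat <- matrix(0, N, n_frames)
  if (N > 0) {
    t_cur <- numeric(N)
    on <- runif(N) < tau_on / (tau_on + tau_off)
    active <- T_end > 0
    while (any(active)) {
      idx <- which(active)
      dwell <- rexp(length(idx)) * ifelse(on[idx], tau_on, tau_off)
      a <- t_cur[idx]
      b <- pmin(a + dwell, T_end[idx])
      sel <- on[idx] & b > a
      if (any(sel)) {
        ei <- idx[sel]; aa <- a[sel]; bb <- b[sel]
        fa <- pmin(floor(aa / dt), n_frames - 1)          # first frame, 0-based
        fb <- pmin(ceiling(bb / dt) - 1, n_frames - 1)    # last frame, 0-based
        for (off in 0:max(fb - fa)) {
          m <- fa + off <= fb
          if (!any(m)) break
          f <- fa[m] + off
          lo <- pmax(aa[m], f * dt)
          hi <- pmin(bb[m], (f + 1) * dt)
          ij <- cbind(ei[m], f + 1L)
          onmat[ij] <- onmat[ij] + (hi - lo)
        }
      }
      t_cur[idx] <- a + dwell
      on[idx] <- !on[idx]
      active[idx] <- t_cur[idx] < T_end[idx]
    }
  }
  emitters$bleach_time_s <- bleach
  emitters$on_fraction <- onmat / dt
  emitters
}

#' Render expected or realized photon counts
#'
#' Converts emitter timecourses into an image stack of photon counts. While
#' on, an emitter emits `photon_rate_per_ms * exposure_ms` expected photons
#' per frame, distributed over pixels as an isotropic 2D Gaussian integrated
#' exactly over each pixel area (Gaussian CDF differences, not point
#' sampling). Gaussian mass falling outside the field of view is lost
#' (physical truncation at the detector edge, no renormalization). A Poisson
#' background is added per pixel, and with `shot_noise = TRUE` the realized
#' counts are Poisson draws of the total expected photons.
#'
#' @param emitters an `emitter_set` with timecourses filled.
#' @param config a [sofi_sim_config()].
#' @param shot_noise if `TRUE` (default) return Poisson-realized counts; if
#'   `FALSE` return the noise-free expected photon stack.
#' @param background include the background term (its mean when
#'   `shot_noise = FALSE`).
#' @return image stack (`height x width x frames`) of photon counts
#'   (integers when `shot_noise = TRUE`).
#' @export
render_photons <- function(emitters, config, shot_noise = TRUE,
                           background = TRUE) {
  stopifnot(inherits(emitters, "emitter_set"), inherits(config, "sofi_sim_config"))
  if (is.null(emitters$on_fraction)) {
    err_input("emitter timecourses missing; run simulate_timecourses() first")
  }
  h <- config$fov_pixels[1]; w <- config$fov_pixels[2]
  n_frames <- config$n_frames
  N <- nrow(emitters$positions)
  sigma_px <- config$psf_sigma_nm / config$pixel_size_nm

  if (N > 0) {
    cx <- emitters$positions$x_nm / config$pixel_size_nm  # pixel units, x = cols
    cy <- emitters$positions$y_nm / config$pixel_size_nm  # y = rows
    wr <- max(3L, ceiling(4 * sigma_px))
    K <- 2L * wr + 1L
    offs <- -wr:wr
    # pixel j (1-based) covers [j-1, j) in pixel units
    Jx <- outer(floor(cx), offs, "+") + 1L
    Iy <- outer(floor(cy), offs, "+") + 1L
    wx <- pnorm((Jx - cx) / sigma_px) - pnorm((Jx - 1 - cx) / sigma_px)
    wy <- pnorm((Iy - cy) / sigma_px) - pnorm((Iy - 1 - cy) / sigma_px)
    iy <- rep(seq_len(K), times = K)
    ix <- rep(seq_len(K), each = K)
    V <- wy[, iy, drop = FALSE] * wx[, ix, drop = FALSE]
    R <- Iy[, iy, drop = FALSE]
    C <- Jx[, ix, drop = FALSE]
    keep <- which(R >= 1L & R <= h & C >= 1L & C <= w & V > 0)
    e <- ((keep - 1L) %% N) + 1L
    W <- Matrix::sparseMatrix(i = (C[keep] - 1L) * h + R[keep], j = e,
                              x = V[keep], dims = c(h * w, N))
    amp <- config$photon_rate_per_ms * config$exposure_ms
    expected <- as.matrix(W %*% (amp * emitters$on_fraction))
  } else {
    expected <- matrix(0, h * w, n_frames)
  }
  if (background) expected <- expected + config$background_photons
  stack <- array(expected, dim = c(h, w, n_frames))
  if (shot_noise) {
    stack <- array(rpois(length(stack), as.numeric(stack)), dim = dim(stack))
  }
  stack
}

#' Apply the EMCCD camera model
#'
#' Converts photon counts to camera counts. In the default `"gamma"` mode
#' each pixel's photons are amplified through the stochastic
#' electron-multiplication register: `amplified ~ Gamma(shape = photons,
#' scale = em_gain)` for positive counts (0 photons give exactly 0), so that
#' `mean(output - offset) = em_gain * mean(photons)`. The `"simple"` mode
#' multiplies deterministically (`offset + em_gain * photons`), which is
#' convenient for analytic tests. Optional additive Gaussian read noise and
#' the constant camera offset complete the model.
#'
#' @param photons image stack of nonnegative integer photon counts.
#' @param config a [sofi_sim_config()]; uses `em_gain`, `em_gain_model`,
#'   `camera_offset`, `read_noise_sd`.
#' @return image stack of camera counts (real-valued).
#' @export
apply_camera <- function(photons, config) {
  stopifnot(inherits(config, "sofi_sim_config"))
  if (any(photons < 0)) err_input("photon counts must be nonnegative")
  if (any(photons != round(photons))) {
    err_input("photon counts must be integers (apply the camera to realized counts)")
  }
  x <- as.numeric(photons)
  out <- numeric(length(x))
  if (config$em_gain_model == "gamma") {
    pos <- x > 0
    out[pos] <- rgamma(sum(pos), shape = x[pos], scale = config$em_gain)
  } else {
    out <- config$em_gain * x
  }
  out <- out + config$camera_offset
  if (config$read_noise_sd > 0) {
    out <- out + rnorm(length(out), sd = config$read_noise_sd)
  }
  array(out, dim = dim(photons))
}

#' Simulate a complete SOFI dataset
#'
#' Runs the full generator: emitter placement on random lines, blinking and
#' photobleaching timecourses, Gaussian-PSF photon rendering with Poisson
#' background and shot noise, and the EMCCD camera model — all from a single
#' seeded RNG stream, so identical seeds give bit-identical outputs.
#'
#' @param config a [sofi_sim_config()]; if `config$seed` is set, the RNG is
#'   seeded before any draw.
#' @return object of class `sofi_simulation`: list with
#'   `stack` (camera counts, `height x width x frames`),
#'   `emitters` (ground truth with timecourses), and
#'   `expected` (noise-free expected-photon stack including the background
#'   mean).
#' @export
#' @examples
#' sim <- simulate_dataset(sofi_sim_config(fov_pixels = c(8, 8), n_frames = 50,
#'                                         n_fluorophores = 100, seed = 42))
#' dim(sim$stack)
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sofi_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  em <- generate_emitters(config)
  em <- simulate_timecourses(em, config)
  expected <- render_photons(em, config, shot_noise = FALSE, background = TRUE)
  photons <- array(rpois(length(expected), as.numeric(expected)),
                   dim = dim(expected))
  stack <- apply_camera(photons, config)
  structure(list(stack = stack, emitters = em, expected = expected,
                 config = config),
            class = "sofi_simulation")
}

#' @export
print.sofi_simulation <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("Simulated SOFI dataset: %d x %d px, %d frames, %d emitters\n",
              d[1], d[2], d[3], nrow(x$emitters$positions)))
  invisible(x)
}
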