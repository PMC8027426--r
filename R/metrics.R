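#' Per-pixel SNR over repeated simulations
#'
#' The signal-to-noise ratio of a SOFI result is the ratio between the value
#' of the signal and the uncertainty of its estimate: per pixel, the mean of
#' the repetition images divided by their standard deviation (sample
#' convention, n - 1). The scalar summary is the mean per-pixel SNR over a
#' foreground mask; pixels with zero standard deviation are excluded from
#' the summary and counted in `n_excluded` (no silent infinities).
#'
#' @param images list of repetition images (`sofi_image` or plain matrices),
#'   all of identical shape; at least 2.
#' @param foreground_mask logical matrix of the same shape selecting the
#'   pixels that enter the scalar summary; `NULL` uses all pixels.
#' @return object of class `sofi_snr`: list with `map` (per-pixel SNR
#'   matrix, `NA` where sd = 0), `summary` (scalar), `n_excluded`.
#' @export
snr_from_repetitions <- function(images, foreground_mask = NULL) {
  if (!is.list(images) || length(images) < 2L) {
    err_input("SNR needs at least 2 repetition images")
  }
  dims <- lapply(images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    err_input("repetition images must all have the same shape")
  }
  arr <- array(unlist(lapply(images, as.numeric)),
               dim = c(dims[[1]], length(images)))
  mu <- rowMeans(arr, dims = 2)
  sdv <- sqrt(apply(arr, c(1, 2), var))
  map <- mu / sdv
  map[sdv == 0] <- NA_real_
  if (is.null(foreground_mask)) {
    foreground_mask <- matrix(TRUE, nrow(mu), ncol(mu))
  }
  if (!identical(dim(foreground_mask), dim(mu))) {
    err_input("foreground_mask shape does not match the images")
  }
  if (!any(foreground_mask)) err_input("foreground mask is empty")
  sel <- foreground_mask & !is.na(map)
  n_excluded <- sum(foreground_mask & is.na(map))
  if (!any(sel)) {
    err_degenerate("all foreground pixels have zero variance across repetitions")
  }
  structure(list(map = map, summary = mean(map[sel]),
                 n_excluded = n_excluded),
            class = "sofi_snr")
}

#' @export
print.sofi_snr <- function(x, ...) {
  cat(sprintf("SOFI SNR: mean foreground SNR = %.3f (%d pixel(s) excluded, sd = 0)\n",
              x$summary, x$n_excluded))
  invisible(x)
}

#' Bleach-free reference SOFI image
#'
#' Builds the reference against which corrected images are compared:
#' the average of `n_reps` second-order SOFI images, each computed from an
#' independent simulation of `n_frames_ref` frames with photodestruction
#' disabled (`tau_bleach_s = Inf`) and independently redrawn emitter
#' geometry. The full-scale protocol averages 100 SOFI images of 5,000-frame
#' sequences; reduced `n_reps`/`n_frames_ref` give a desk-scale reference.
#'
#' @param config a [sofi_sim_config()]; its `tau_bleach_s` is overridden
#'   with `Inf` and `n_frames` with `n_frames_ref`.
#' @param n_reps number of independent repetitions to average (default 100).
#' @param n_frames_ref frames per repetition (default 5000).
#' @param seeds optional integer vector of per-repetition seeds (length
#'   `n_reps`); `NULL` uses the current RNG stream.
#' @return a [sofi_image][new_sofi_image] tagged `"reference"`.
#' @export
compute_reference <- function(config, n_reps = 100L, n_frames_ref = 5000L,
                              seeds = NULL) {
  stopifnot(inherits(config, "sofi_sim_config"))
  if (!is.null(seeds) && length(seeds) != n_reps) {
    err_spec("seeds must have length n_reps")
  }
  cfg <- config
  cfg$tau_bleach_s <- Inf
  cfg$n_frames <- as.integer(n_frames_ref)
  acc <- 0
  for (r in seq_len(n_reps)) {
    cfg$seed <- if (is.null(seeds)) NULL else seeds[r]
    sim <- simulate_dataset(cfg)
    acc <- acc + unclass(second_order_crosscumulant(sim$stack))
  }
  new_sofi_image(acc / n_reps, source = "reference")
}

#' Root-mean-square deviation between SOFI images
#'
#' Measures the accuracy of a correction method against a bleach-free
#' reference. Because SOFI amplitudes differ across methods by an arbitrary
#' scale, both images are first normalized to unit Euclidean (Frobenius)
#' norm; the RMSD is then the square root of the mean squared pixel
#' difference. The normalization is recorded on the result.
#'
#' @param image,reference SOFI images (or matrices) of identical shape.
#' @return scalar RMSD with attribute `normalization = "unit Euclidean norm"`.
#' @export
#' @examples
#' a <- matrix(1:9, 3); b <- matrix(9:1, 3)
#' sofi_rmsd(a, b)
#' sofi_rmsd(2 * a, a)   # 0: scale is removed
sofi_rmsd <- function(image, reference) {
  a <- as.matrix(unclass(image)); b <- as.matrix(unclass(reference))
  if (!identical(dim(a), dim(b))) {
    err_input("image and reference must have identical shapes")
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    err_degenerate("cannot normalize a zero-norm image for RMSD")
  }
  structure(sqrt(mean((a / na - b / nb)^2)),
            normalization = "unit Euclidean norm")
}

# Deterministic sub-seed streams: one base seed fans out into independent,
# reproducible per-task seeds (all < 2^31).
derive_seeds <- function(seed, n) {
  r <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(r)) assign(".Random.seed", r, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Compare trend-correction methods by SNR and RMSD
#'
#' Reduced-scale reproduction of the method-comparison protocol: for each
#' photobleaching survival time in `tau_grid` and each correction method,
#' `n_repetitions` independent datasets are simulated, the SOFI pipeline is
#' run, the SNR is computed across repetitions (foreground mask from the
#' bleach-free reference), and the RMSD against the reference is averaged
#' over repetitions. All methods are applied to the same simulated datasets
#' (paired comparison).
#'
#' @param tau_grid numeric vector of survival times in seconds
#'   (e.g. `c(1.1, 5.5, 11, 33)`).
#' @param methods subset of `c("none", "batch", "whittaker")`.
#' @param n_repetitions independent simulations per condition (>= 2).
#' @param config base [sofi_sim_config()] (its `tau_bleach_s` and `seed` are
#'   overridden per condition).
#' @param batch_size batch length for the batching method.
#' @param lambda smoothing parameter or `"auto"` for the Whittaker method.
#' @param n_ref_reps,n_ref_frames reference protocol size (see
#'   [compute_reference()]).
#' @param mask_quantile foreground threshold: pixels of the reference above
#'   `mask_quantile` times its maximum form the SNR mask (default 0.1).
#' @param seed base seed; all per-repetition seeds are derived from it
#'   deterministically, so the whole table is reproducible.
#' @return object of class `sofi_evaluation`: list with `results` (tibble
#'   with columns `tau_bleach_s`, `method`, `n_reps`, `snr`, `rmsd`,
#'   `lambda`, `seed`), `reference` (the reference image), and `images`
#'   (per-condition mean SOFI images). `tidy()` returns the results tibble.
#' @export
evaluate_methods <- function(tau_grid,
                             methods = c("none", "batch", "whittaker"),
                             n_repetitions = 20L,
                             config = sofi_sim_config(),
                             batch_size = 50L,
                             lambda = "auto",
                             n_ref_reps = 10L,
                             n_ref_frames = 1000L,
                             mask_quantile = 0.1,
                             seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_repetitions < 2L) err_spec("n_repetitions must be >= 2 for SNR")
  if (!is.numeric(tau_grid) || length(tau_grid) < 1L || any(tau_grid <= 0)) {
    err_spec("tau_grid must contain positive survival times (seconds)")
  }

  all_seeds <- derive_seeds(seed, n_ref_reps + length(tau_grid) * n_repetitions)
  ref_seeds <- all_seeds[seq_len(n_ref_reps)]
  sim_seeds <- matrix(all_seeds[-seq_len(n_ref_reps)],
                      nrow = n_repetitions)

  reference <- compute_reference(config, n_reps = n_ref_reps,
                                 n_frames_ref = n_ref_frames,
                                 seeds = ref_seeds)
  mask <- unclass(reference) > mask_quantile * max(reference)

  rows <- list(); images <- list()
  for (ti in seq_along(tau_grid)) {
    tau <- tau_grid[ti]
    cfg <- config
    cfg$tau_bleach_s <- tau
    per_method <- lapply(methods, function(m) vector("list", n_repetitions))
    names(per_method) <- methods
    lambdas <- rep(NA_real_, n_repetitions)
    for (r in seq_len(n_repetitions)) {
      cfg$seed <- sim_seeds[r, ti]
      sim <- simulate_dataset(cfg)
      for (m in methods) {
        img <- sofi_pipeline(sim$stack, mode = m, batch_size = batch_size,
                             lambda = lambda)
        per_method[[m]][[r]] <- img
        if (m == "whittaker") lambdas[r] <- attr(img, "lambda")
      }
    }
    for (m in methods) {
      imgs <- per_method[[m]]
      snr <- snr_from_repetitions(imgs, foreground_mask = mask)
      rmsd_vals <- vapply(imgs, function(im) as.numeric(sofi_rmsd(im, reference)),
                          numeric(1))
      mean_img <- Reduce(`+`, lapply(imgs, unclass)) / length(imgs)
      images[[sprintf("tau%.3g_%s", tau, m)]] <-
        new_sofi_image(mean_img, source = attr(imgs[[1]], "source"),
                       batch_size = attr(imgs[[1]], "batch_size"))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tau_bleach_s = tau, method = m, n_reps = n_repetitions,
        snr = snr$summary, rmsd = mean(rmsd_vals),
        lambda = if (m == "whittaker") stats::median(lambdas) else NA_real_,
        seed = seed)
    }
  }
  structure(list(results = dplyr::bind_rows(rows), reference = reference,
                 images = images, mask = mask),
            class = "sofi_evaluation")
}

#' @export
print.sofi_evaluation <- function(x, ...) {
  cat("SOFI method evaluation\n")
  print(x$results)
  invisible(x)
}

#' @rdname evaluate_methods
#' @param x,object a `sofi_evaluation`.
#' @param ... unused.
#' @export
tidy.sofi_evaluation <- function(x, ...) x$results

#' @rdname evaluate_methods
#' @export
glance.sofi_evaluation <- function(x, ...) {
  tibble::tibble(n_conditions = length(unique(x$results$tau_bleach_s)),
                 n_methods = length(unique(x$results$method)),
                 n_reps = x$results$n_reps[1])
}

#' @rdname evaluate_methods
#' @export
autoplot.sofi_evaluation <- function(object, ...) {
  df <- tidyr_longer_metrics(object$results)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$tau_bleach_s),
                                   y = .data$value,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~.data$metric, scales = "free_y") +
    ggplot2::labs(x = "photobleaching survival time (s)", y = NULL,
                  fill = "correction") +
    ggplot2::theme_minimal()
}

# long format for plotting without importing tidyr
tidyr_longer_metrics <- function(res) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::select(res, "tau_bleach_s", "method", value = "snr"),
                  metric = "SNR"),
    dplyr::mutate(dplyr::select(res, "tau_bleach_s", "method", value = "rmsd"),
                  metric = "RMSD"))
}
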