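# TIFF I/O. Reading goes through tiff::readTIFF, which handles both integer
# and IEEE-float sample formats. Writing 16-bit unsigned data goes through
# tiff::writeTIFF. Float32 output (needed for trend-corrected stacks and
# cumulant images, which are negative-valued and unbounded) is written by a
# minimal baseline-TIFF writer below, because tiff::writeTIFF only stores
# [0,1]-scaled integer samples.

# Uncompressed little-endian baseline TIFF, one strip per page,
# SampleFormat = IEEE float, 32 bits per sample.
write_float_tiff <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  nbytes <- h * w * 4L
  n <- length(frames)
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_off <- 8L + (seq_len(n) - 1L) * nbytes
  ifd_off <- 8L + n * nbytes + (seq_len(n) - 1L) * ifd_size

  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off[1], con, size = 4, endian = "little")
  for (fr in frames) {
    writeBin(as.numeric(t(fr)), con, size = 4, endian = "little")
  }
  entry <- function(tag, type, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  for (i in seq_len(n)) {
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256, 4, w)              # ImageWidth
    entry(257, 4, h)              # ImageLength
    entry(258, 3, 32)             # BitsPerSample
    entry(259, 3, 1)              # Compression: none
    entry(262, 3, 1)              # Photometric: BlackIsZero
    entry(273, 4, data_off[i])    # StripOffsets
    entry(278, 4, h)              # RowsPerStrip
    entry(279, 4, nbytes)         # StripByteCounts
    entry(339, 3, 3)              # SampleFormat: IEEE float
    writeBin(as.integer(if (i < n) ifd_off[i + 1L] else 0L),
             con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' Frames are returned in page (acquisition) order. Integer pixel data are
#' returned as stored (counts); float pages are returned at float32
#' precision. All pages must share one shape.
#'
#' @param path path to a TIFF file.
#' @return image stack (`height x width x frames`).
#' @export
read_stack <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    err_format(sprintf("'%s' does not exist or is empty", path))
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) {
      # as.is is unsupported for float images; floats come back as stored
      tryCatch(tiff::readTIFF(path, all = TRUE),
               error = function(e2) err_format(
                 sprintf("cannot read '%s' as TIFF: %s", path, conditionMessage(e2))))
    })
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) err_format(sprintf("'%s' contains no pages", path))
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), d1)) {
      err_format(sprintf("page %d has shape %s, expected %s", i,
                         paste(dim(pages[[i]]), collapse = "x"),
                         paste(d1, collapse = "x")))
    }
  }
  array(unlist(pages), dim = c(d1[1], d1[2], length(pages)))
}

#' Write an image stack to a multi-page TIFF
#'
#' `dtype = "uint16"` stores integer counts (0..65535); negative values are
#' refused explicitly rather than clipped. `dtype = "float32"` stores IEEE
#' floats and preserves negative values (trend-corrected data). A JSON
#' sidecar (`<path>.json`) records provenance; pass run-specific fields via
#' `sidecar`.
#'
#' @param stack image stack (`height x width x frames`).
#' @param path output path.
#' @param dtype `"uint16"` or `"float32"`.
#' @param sidecar named list of extra provenance fields, or `NULL` to skip
#'   the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dtype = c("float32", "uint16"),
                        sidecar = list()) {
  check_stack(stack)
  dtype <- match.arg(dtype)
  frames <- lapply(seq_len(dim(stack)[3]),
                   function(i) stack[, , i, drop = TRUE])
  if (dtype == "uint16") {
    if (min(stack) < 0) {
      err_input("stack contains negative values; use dtype = 'float32'")
    }
    if (max(stack) > 65535 || any(stack != round(stack))) {
      err_input("uint16 requires integer values in [0, 65535]")
    }
    tiff::writeTIFF(lapply(frames, function(f) f / 65535), path,
                    bits.per.sample = 16L, reduce = FALSE)
  } else {
    write_float_tiff(frames, path)
  }
  if (!is.null(sidecar)) {
    meta <- c(list(package = "sofitrend",
                   version = as.character(utils::packageVersion("sofitrend")),
                   dtype = dtype, n_frames = dim(stack)[3],
                   shape = dim(stack)[1:2]),
              sidecar)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a single image (e.g. a SOFI cumulant image) as float32 TIFF
#'
#' @param image numeric matrix or `sofi_image`.
#' @param path output path.
#' @param sidecar named list of extra provenance fields, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, sidecar = list()) {
  meta0 <- list()
  if (inherits(image, "sofi_image")) {
    meta0 <- list(source = attr(image, "source"),
                  order = attr(image, "order"),
                  batch_size = attr(image, "batch_size"),
                  lambda = attr(image, "lambda"),
                  cross_scheme = attr(image, "cross_scheme"))
    meta0 <- meta0[!vapply(meta0, is.null, logical(1))]
  }
  m <- as.matrix(unclass(image))
  write_float_tiff(list(m), path)
  if (!is.null(sidecar)) {
    meta <- c(list(package = "sofitrend",
                   version = as.character(utils::packageVersion("sofitrend")),
                   dtype = "float32", shape = dim(m)),
              meta0, sidecar)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a simulation configuration from JSON or YAML
#'
#' The file holds any subset of the [sofi_sim_config()] arguments; missing
#' fields take the defaults, unknown fields are an error.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a validated [sofi_sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) err_format(sprintf("'%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    err_format(sprintf("unsupported config extension '%s' (use json/yaml)", ext)))
  if (!is.list(vals)) err_format("config file must contain a mapping")
  known <- names(formals(sofi_sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    err_format(sprintf("unknown config field(s): %s",
                       paste(unknown, collapse = ", ")))
  }
  do.call(sofi_sim_config, vals)
}

#' Export V-curve diagnostics as CSV
#'
#' Writes the per-lambda diagnostics (columns `lambda`, `log10_fit`,
#' `log10_penalty`, `v`) of a [select_lambda_vcurve()] result.
#'
#' @param selection a `vcurve_selection`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vcurve_csv <- function(selection, path) {
  stopifnot(inherits(selection, "vcurve_selection"))
  utils::write.csv(selection$diagnostics, path, row.names = FALSE)
  invisible(path)
}

#' Export emitter ground truth as CSV
#'
#' Columns: `x_nm`, `y_nm`, `line`, `bleach_time_s` (when present).
#'
#' @param emitters an `emitter_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_emitters_csv <- function(emitters, path) {
  stopifnot(inherits(emitters, "emitter_set"))
  utils::write.csv(tidy.emitter_set(emitters), path, row.names = FALSE)
  invisible(path)
}
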