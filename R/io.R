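#' Read a TIFF image or movie as numeric arrays
#'
#' Frames are returned in acquisition order with their stored integer values
#' preserved. The pixel size is deliberately *not* read from TIFF tags (tag
#' dialects are unreliable); supply it from your configuration.
#'
#' @param path Path to a single- or multi-page TIFF.
#' @return A matrix (single page) or a 3-D array `ny x nx x n_frames`.
#' @seealso [write_image_stack()]
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'.", path))
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                     error = function(e) {
                       abort(sprintf("Could not read TIFF '%s': %s", path,
                                     conditionMessage(e)))
                     })
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) == 1L) return(frames[[1L]] * 1.0)
  arr <- array(0, dim = c(dim(frames[[1L]]), length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  arr
}

#' Write a numeric image or movie as 16-bit multi-page TIFF
#'
#' Values are rounded and clamped to the 16-bit range \[0, 65535\];
#' integer-valued input in range round-trips bit-identically through
#' [read_image_stack()].
#'
#' @param x Matrix or 3-D array (`ny x nx x n_frames`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(x, path) {
  frames <- if (is.matrix(x)) list(x) else {
    stopifnot(is.array(x), length(dim(x)) == 3L)
    purrr::map(seq_len(dim(x)[3]), function(f) x[, , f])
  }
  frames <- purrr::map(frames, function(m) pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

# Default run configuration: every tunable named by the analysis functions.
default_config <- function() {
  list(
    stage = NULL,
    seed = 1L,
    out_dir = ".",
    verbose = FALSE,
    preset = NULL,
    input = NULL,   # path to profiles/movie/detections/particles input
    input_b = NULL, # second channel for coloc
    imaging = list(pixel_size = 133, psf_fwhm = 266, background = 10,
                   photon_scale = 1, read_noise_sd = 2,
                   field_size = c(20, 20)),
    profile = list(min_prominence_frac = 0.2, min_separation_nm = 200,
                   resolution_limit = 266, width_definition = "fwhm"),
    frap = list(frame_interval_s = 5, r_excl_nm = 500, k_before = 2,
                k_after = 4, d_max_nm = 400, margin_frac = 0.2,
                sigma_px = 1.7, threshold_frac = 0.2),
    track = list(frame_interval_s = 5, d_max_nm = 400, max_gap = 1,
                 min_track_len = 5, method = "slope", sigma_px = 1.7,
                 threshold_frac = 0.3),
    coloc = list(threshold_a = NULL, threshold_b = NULL),
    gold = list(axis_length = NULL, mode = "uniform", n = 100,
                golgi_length = 1000, concentration = 3)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration file, fills documented defaults,
#' and rejects unknown keys by name. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a YAML/JSON file, or `NULL` for pure defaults.
#' @return A named list of class `run_config`.
#' @examples
#' cfg <- load_config(NULL)
#' cfg$imaging$psf_fwhm
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("No such config file: '%s'.", path))
    user <- yaml::read_yaml(path) %||% list()
  }
  cfg <- merge_config(defaults, user, prefix = NULL)
  cfg$imaging$field_size <- as.numeric(unlist(cfg$imaging$field_size))
  # field-level validation (constructors raise named errors)
  imaging_params(
    pixel_size = cfg$imaging$pixel_size, psf_fwhm = cfg$imaging$psf_fwhm,
    background = cfg$imaging$background, photon_scale = cfg$imaging$photon_scale,
    read_noise_sd = cfg$imaging$read_noise_sd,
    field_size = unlist(cfg$imaging$field_size)
  )
  check_number(cfg$profile$min_prominence_frac, "profile.min_prominence_frac",
               min = 0, max = 1)
  check_number(cfg$profile$resolution_limit, "profile.resolution_limit",
               min = 0, strict_min = TRUE)
  check_number(cfg$frap$margin_frac, "frap.margin_frac", min = 0, max = 0.5)
  structure(cfg, class = "run_config")
}

# Recursive default-filling merge; unknown keys are an error.
merge_config <- function(defaults, user, prefix) {
  if (!is.list(user)) abort("Configuration must be a mapping of named keys.")
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    key <- if (is.null(prefix)) extra[1] else paste(prefix, extra[1], sep = ".")
    abort(sprintf("Unknown configuration key: '%s'.", key))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    prefix = if (is.null(prefix)) k else paste(prefix, k, sep = "."))
    } else {
      defaults[k] <- list(user[[k]]) # keeps explicit-NULL values in place
    }
  }
  defaults
}

#' Serialize a configuration back to YAML
#'
#' @param config A `run_config` list.
#' @param path Output path; `NULL` returns the YAML text.
#' @return The YAML text (invisibly when written to `path`).
#' @export
write_config <- function(config, path = NULL) {
  txt <- yaml::as.yaml(unclass(config))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
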