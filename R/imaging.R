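#' Imaging parameters for simulation and analysis
#'
#' Bundles the optical and camera parameters shared by all synthetic-data
#' generators and by the physical-unit conversions in the analysis functions.
#' The point-spread function (PSF) is modelled as an isotropic Gaussian whose
#' full width at half maximum defaults to 266 nm, the resolution limit of a
#' spinning-disc confocal with a high-NA oil objective; the default pixel size
#' of 133 nm samples that PSF at the Nyquist rate.
#'
#' @param pixel_size Pixel size in nm/pixel. Default 133.
#' @param psf_fwhm PSF full width at half maximum in nm. Must be at least
#'   `pixel_size`. Default 266.
#' @param background Constant background level in arbitrary units. Default 10.
#' @param photon_scale Photon conversion factor for the Poisson noise model:
#'   expected photons per intensity unit. `0` disables Poisson noise.
#'   Default 1.
#' @param read_noise_sd Standard deviation of additive Gaussian read noise in
#'   intensity units. `0` disables it. Default 2.
#' @param field_size Numeric length-2 vector, field of view (width, height)
#'   in micrometres. Default `c(20, 20)` (a 400 square-micrometre membrane
#'   patch).
#'
#' @return An object of class `imaging_params` (a named list).
#' @examples
#' imaging_params()
#' imaging_params(psf_fwhm = 300, photon_scale = 0, read_noise_sd = 0)
#' @export
imaging_params <- function(pixel_size = 133, psf_fwhm = 266, background = 10,
                           photon_scale = 1, read_noise_sd = 2,
                           field_size = c(20, 20)) {
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_number(psf_fwhm, "psf_fwhm", min = pixel_size)
  check_number(background, "background", min = 0)
  check_number(photon_scale, "photon_scale", min = 0)
  check_number(read_noise_sd, "read_noise_sd", min = 0)
  if (!is.numeric(field_size) || length(field_size) != 2L || any(field_size <= 0)) {
    abort("`field_size` must be two positive numbers (width, height) in um.")
  }
  structure(
    list(pixel_size = pixel_size, psf_fwhm = psf_fwhm, background = background,
         photon_scale = photon_scale, read_noise_sd = read_noise_sd,
         field_size = as.numeric(field_size)),
    class = "imaging_params"
  )
}

#' @export
print.imaging_params <- function(x, ...) {
  cat("<imaging_params>\n")
  cat(sprintf("  pixel size    : %g nm/px\n", x$pixel_size))
  cat(sprintf("  PSF FWHM      : %g nm (sigma %.1f nm)\n", x$psf_fwhm, psf_sigma(x)))
  cat(sprintf("  background    : %g a.u.\n", x$background))
  cat(sprintf("  photon scale  : %g, read noise sd %g a.u.\n",
              x$photon_scale, x$read_noise_sd))
  cat(sprintf("  field         : %g x %g um\n", x$field_size[1], x$field_size[2]))
  invisible(x)
}

# FWHM -> Gaussian sigma conversion factor 2*sqrt(2*log(2)) = 2.3548...
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

psf_sigma <- function(imaging) imaging$psf_fwhm / FWHM_FACTOR

# Apply the camera noise model to a clean signal (vector, matrix or array):
# Poisson on photon_scale * signal, rescaled back, plus Gaussian read noise.
# Noise is a no-op when both photon_scale and read_noise_sd are zero.
apply_noise <- function(signal, imaging) {
  out <- signal
  if (imaging$photon_scale > 0) {
    lam <- pmax(signal * imaging$photon_scale, 0)
    counts <- rpois(length(lam), lam) / imaging$photon_scale
    out <- if (is.null(dim(signal))) counts else array(counts, dim = dim(signal))
  }
  if (imaging$read_noise_sd > 0) {
    out <- out + rnorm(length(out), 0, imaging$read_noise_sd)
  }
  out
}
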