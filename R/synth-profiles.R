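#' Specify a synthetic Golgi population
#'
#' Describes a population of Golgi bodies imaged by confocal microscopy of a
#' fluorescent CesA cargo. A fraction of the population is "solid"
#' (sub-resolution cargo concentrated at the Golgi centre, one apparent peak
#' on a transect) and the rest is "ring-shaped" (cargo at the cisternal rim,
#' two peaks separated by the ring diameter).
#'
#' @param n_objects Number of Golgi bodies.
#' @param solid_fraction Proportion of solid (single-peak) bodies, in
#'   \[0, 1\].
#' @param ring_diameter_mean,ring_diameter_sd Mean and SD of the true ring
#'   diameter in nm (normal, truncated below at the PSF FWHM so every
#'   generated ring is resolvable).
#' @param ring_amplitude,solid_amplitude Peak amplitude of the clean signal,
#'   in a.u. above background.
#' @param seed Integer seed; every generator call with the same spec and seed
#'   is bit-reproducible.
#'
#' @return A `golgi_population_spec` object.
#' @examples
#' golgi_population_spec(100, solid_fraction = 0.5, seed = 1)
#' @export
golgi_population_spec <- function(n_objects, solid_fraction,
                                  ring_diameter_mean = 800,
                                  ring_diameter_sd = 150,
                                  ring_amplitude = 100,
                                  solid_amplitude = 100,
                                  seed = NULL) {
  n_objects <- check_count(n_objects, "n_objects", min = 0L)
  check_number(solid_fraction, "solid_fraction", min = 0, max = 1)
  check_number(ring_diameter_mean, "ring_diameter_mean", min = 0, strict_min = TRUE)
  check_number(ring_diameter_sd, "ring_diameter_sd", min = 0)
  check_number(ring_amplitude, "ring_amplitude", min = 0)
  check_number(solid_amplitude, "solid_amplitude", min = 0)
  structure(
    list(n_objects = n_objects, solid_fraction = solid_fraction,
         ring_diameter_mean = ring_diameter_mean,
         ring_diameter_sd = ring_diameter_sd,
         ring_amplitude = ring_amplitude, solid_amplitude = solid_amplitude,
         seed = seed),
    class = "golgi_population_spec"
  )
}

# Clean double/single-Gaussian transect model evaluated at positions x (nm).
profile_model <- function(x, b, A1, mu1, sigma1, A2 = 0, mu2 = 0, sigma2 = 1) {
  b + A1 * exp(-(x - mu1)^2 / (2 * sigma1^2)) +
    A2 * exp(-(x - mu2)^2 / (2 * sigma2^2))
}

# Sampling grid for a transect: step = pixel_size/2, centred on 0,
# total length `length_nm` (default 2660 nm, i.e. a ~2.7 um window).
profile_positions <- function(imaging, length_nm = 2660) {
  step <- imaging$pixel_size / 2
  half <- floor((length_nm / 2) / step)
  seq(-half, half) * step
}

#' Generate cross-sectional intensity profiles with known ground truth
#'
#' Emulates 1D intensity transects drawn through the centres of Golgi bodies.
#' A ring of true diameter D appears as two Gaussians centred at +/- D/2, a
#' solid body as a single Gaussian at 0; in both cases the Gaussian width is
#' set by the PSF (`sigma = psf_fwhm / (2 sqrt(2 ln 2))`). A constant
#' background plus Poisson/Gaussian camera noise is applied (disable by
#' setting `photon_scale = 0, read_noise_sd = 0` in `imaging`).
#'
#' @param spec A [golgi_population_spec()].
#' @param imaging An [imaging_params()] object.
#' @param length_nm Transect window length in nm (default 2660); samples are
#'   spaced `pixel_size / 2` apart.
#'
#' @return A list with
#'   * `profiles`: tibble with columns `source_id`, `position_nm`,
#'     `intensity` (one block of rows per object), and
#'   * `truth`: tibble with `source_id`, `class` (`"ring"`/`"solid"`),
#'     `true_diameter_nm` (`NA` for solids).
#' @examples
#' sim <- generate_profile_population(
#'   golgi_population_spec(5, solid_fraction = 0.4, seed = 1),
#'   imaging_params()
#' )
#' head(sim$profiles)
#' sim$truth
#' @export
generate_profile_population <- function(spec, imaging = imaging_params(),
                                        length_nm = 2660) {
  stopifnot(inherits(spec, "golgi_population_spec"),
            inherits(imaging, "imaging_params"))
  if (spec$ring_diameter_mean <= imaging$psf_fwhm) {
    abort("`ring_diameter_mean` must exceed `psf_fwhm`: rings must be resolvable by construction.")
  }
  local_seed(spec$seed)
  x <- profile_positions(imaging, length_nm)
  sig <- psf_sigma(imaging)
  n <- spec$n_objects

  is_solid <- runif(n) < spec$solid_fraction
  diam <- rep(NA_real_, n)
  n_ring <- sum(!is_solid)
  if (n_ring > 0) {
    d <- rnorm(n_ring, spec$ring_diameter_mean, spec$ring_diameter_sd)
    # truncate below at the PSF FWHM (resolvable by construction)
    while (any(d <= imaging$psf_fwhm)) {
      k <- d <= imaging$psf_fwhm
      d[k] <- rnorm(sum(k), spec$ring_diameter_mean, spec$ring_diameter_sd)
    }
    diam[!is_solid] <- d
  }

  ids <- sprintf("obj%04d", seq_len(n))
  profiles <- purrr::map(seq_len(n), function(i) {
    clean <- if (is_solid[i]) {
      profile_model(x, imaging$background, spec$solid_amplitude, 0, sig)
    } else {
      profile_model(x, imaging$background,
                    spec$ring_amplitude, -diam[i] / 2, sig,
                    spec$ring_amplitude, diam[i] / 2, sig)
    }
    tibble(source_id = ids[i], position_nm = x, intensity = apply_noise(clean, imaging))
  }) |> purrr::list_rbind()

  truth <- tibble(
    source_id = ids,
    class = ifelse(is_solid, "solid", "ring"),
    true_diameter_nm = diam
  )
  list(profiles = profiles, truth = truth)
}
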