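# Non-overlapping uniform placement with a minimum pairwise distance and an
# edge margin; rejection sampling with a bounded number of attempts.
place_centres <- function(n, w_nm, h_nm, min_dist_nm, margin_nm,
                          max_tries = 2000L) {
  if (n == 0L) return(tibble(x_nm = numeric(), y_nm = numeric()))
  if (w_nm <= 2 * margin_nm || h_nm <= 2 * margin_nm) {
    abort("Field too small to place objects inside the margin.")
  }
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, margin_nm, w_nm - margin_nm)
      y <- runif(1, margin_nm, h_nm - margin_nm)
      if (!length(xs) || min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_dist_nm) {
        xs <- c(xs, x); ys <- c(ys, y); ok <- TRUE; break
      }
    }
    if (!ok) {
      abort(sprintf(
        "Could not place %d objects without overlap (min distance %g nm) in a %g x %g nm field.",
        n, min_dist_nm, w_nm, h_nm))
    }
  }
  tibble(x_nm = xs, y_nm = ys)
}

# Render a thin ring of diameter d_nm as a circle of point sources convolved
# with the Gaussian PSF. Total flux equals that of a solid spot of the same
# amplitude (amp * 2 pi sigma^2 in intensity-pixel units), so integrated
# intensity is independent of diameter.
stamp_ring <- function(img, cx, cy, d_nm, amp, sigma_px, pixel_size) {
  sigma_nm <- sigma_px * pixel_size
  n_pts <- max(16L, ceiling(pi * d_nm / (sigma_nm / 3)))
  th <- (seq_len(n_pts) - 1) / n_pts * 2 * pi
  r_px <- d_nm / 2 / pixel_size
  flux_per_pt <- amp / n_pts # peak-equivalent flux split over the rim sources
  for (k in seq_len(n_pts)) {
    img <- stamp_spot(img, cx + r_px * cos(th[k]), cy + r_px * sin(th[k]),
                      flux_per_pt, sigma_px)
  }
  img
}

#' Generate a 2D field of ring-shaped and solid Golgi bodies
#'
#' Renders a fluorescence image of a Golgi population on a pixel grid. Solid
#' bodies are single sub-resolution point sources convolved with the
#' Gaussian PSF; rings are circles of point sources (infinitesimally thin
#' rim) convolved with the same PSF, normalized so that a ring's integrated
#' intensity is independent of its diameter. Objects are placed uniformly
#' without overlap (minimum centre distance twice the largest diameter).
#'
#' @inheritParams generate_profile_population
#' @return A list with `image` (matrix, rows = y, cols = x, a.u.) and
#'   `truth` (tibble: `object_id`, `class`, `true_diameter_nm`, `x_nm`,
#'   `y_nm`, `orientation_rad` — orientation is `NA` for the isotropic
#'   objects generated here).
#' @examples
#' sim <- generate_golgi_image(golgi_population_spec(3, 0.5, seed = 2),
#'                             imaging_params(photon_scale = 0, read_noise_sd = 0))
#' dim(sim$image)
#' @export
generate_golgi_image <- function(spec, imaging = imaging_params()) {
  stopifnot(inherits(spec, "golgi_population_spec"),
            inherits(imaging, "imaging_params"))
  if (spec$ring_diameter_mean <= imaging$psf_fwhm) {
    abort("`ring_diameter_mean` must exceed `psf_fwhm`: rings must be resolvable by construction.")
  }
  local_seed(spec$seed)
  px <- imaging$pixel_size
  nx <- floor(imaging$field_size[1] * 1000 / px)
  ny <- floor(imaging$field_size[2] * 1000 / px)
  sigma_px <- psf_sigma(imaging) / px
  n <- spec$n_objects

  is_solid <- runif(n) < spec$solid_fraction
  diam <- rep(NA_real_, n)
  if (any(!is_solid)) {
    d <- rnorm(sum(!is_solid), spec$ring_diameter_mean, spec$ring_diameter_sd)
    while (any(d <= imaging$psf_fwhm)) {
      k <- d <= imaging$psf_fwhm
      d[k] <- rnorm(sum(k), spec$ring_diameter_mean, spec$ring_diameter_sd)
    }
    diam[!is_solid] <- d
  }
  max_d <- max(c(diam, imaging$psf_fwhm), na.rm = TRUE)
  centres <- place_centres(n, nx * px, ny * px,
                           min_dist_nm = 2 * max_d,
                           margin_nm = max_d + 2 * imaging$psf_fwhm)

  img <- matrix(imaging$background, nrow = ny, ncol = nx)
  for (i in seq_len(n)) {
    cx <- nm_to_px(centres$x_nm[i], px)
    cy <- nm_to_px(centres$y_nm[i], px)
    if (is_solid[i]) {
      img <- stamp_spot(img, cx, cy, spec$solid_amplitude, sigma_px)
    } else {
      img <- stamp_ring(img, cx, cy, diam[i], spec$ring_amplitude, sigma_px, px)
    }
  }
  img <- apply_noise(img, imaging)

  truth <- tibble(
    object_id = if (n) sprintf("obj%04d", seq_len(n)) else character(),
    class = ifelse(is_solid, "solid", "ring"),
    true_diameter_nm = diam,
    x_nm = centres$x_nm, y_nm = centres$y_nm,
    orientation_rad = NA_real_
  )
  list(image = img, truth = truth)
}

#' Generate a registered two-channel image pair with known co-occurrence
#'
#' Each channel contains `n_objects` diffraction-limited spots; a fraction
#' `overlap_fraction` of them sit at identical positions in both channels,
#' the rest are channel-exclusive and placed disjointly. The design oracle:
#' with equal-intensity spots and no noise, the Manders coefficients equal
#' `overlap_fraction`.
#'
#' @param n_objects Spots per channel.
#' @param overlap_fraction Fraction of each channel's spots shared with the
#'   other channel, in \[0, 1\].
#' @param imaging An [imaging_params()].
#' @param amplitude Spot peak amplitude, a.u. (default 100).
#' @param seed Integer seed.
#' @return A list with `channel_a`, `channel_b` (matrices) and `truth`
#'   (tibble: `object_id`, `membership` in `"both"`/`"a_only"`/`"b_only"`,
#'   `x_nm`, `y_nm`).
#' @examples
#' pair <- generate_coloc_pair(6, 0.5, imaging_params(photon_scale = 0,
#'                             read_noise_sd = 0, background = 0), seed = 3)
#' pair$truth
#' @export
generate_coloc_pair <- function(n_objects, overlap_fraction,
                                imaging = imaging_params(), amplitude = 100,
                                seed = NULL) {
  n_objects <- check_count(n_objects, "n_objects", min = 0L)
  check_number(overlap_fraction, "overlap_fraction", min = 0, max = 1)
  check_number(amplitude, "amplitude", min = 0)
  local_seed(seed)
  px <- imaging$pixel_size
  nx <- floor(imaging$field_size[1] * 1000 / px)
  ny <- floor(imaging$field_size[2] * 1000 / px)
  sigma_px <- psf_sigma(imaging) / px

  n_both <- round(overlap_fraction * n_objects)
  n_excl <- n_objects - n_both # per channel
  n_sites <- n_both + 2L * n_excl
  sites <- place_centres(n_sites, nx * px, ny * px,
                         min_dist_nm = 8 * imaging$psf_fwhm,
                         margin_nm = 4 * imaging$psf_fwhm)
  membership <- c(rep("both", n_both), rep("a_only", n_excl), rep("b_only", n_excl))

  render <- function(keep) {
    img <- matrix(imaging$background, nrow = ny, ncol = nx)
    for (i in which(keep)) {
      img <- stamp_spot(img, nm_to_px(sites$x_nm[i], px),
                        nm_to_px(sites$y_nm[i], px), amplitude, sigma_px)
    }
    apply_noise(img, imaging)
  }
  channel_a <- render(membership != "b_only")
  channel_b <- render(membership != "a_only")

  truth <- tibble(
    object_id = if (n_sites) sprintf("site%04d", seq_len(n_sites)) else character(),
    membership = membership, x_nm = sites$x_nm, y_nm = sites$y_nm
  )
  list(channel_a = channel_a, channel_b = channel_b, truth = truth)
}
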