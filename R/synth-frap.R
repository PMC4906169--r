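#' Specify a synthetic FRAP delivery experiment
#'
#' Describes a post-bleach time-lapse of a plasma-membrane patch into which
#' new CesA foci are inserted by a homogeneous Poisson process. Inserted foci
#' persist for the rest of the movie and translate at a constant speed
#' (the characteristic tracking behaviour of active complexes). Optional
#' "decoy" flashes last exactly one frame and emulate transient
#' non-delivery events that the persistence criterion must reject.
#'
#' @param true_rate Insertion rate in events per square micrometre per hour.
#' @param frame_interval Acquisition interval in seconds (default 5).
#' @param duration Movie duration in seconds (default 600, i.e. 10 min).
#' @param track_speed Post-insertion speed of each focus in nm/min
#'   (default 255).
#' @param decoy_density Rate of one-frame decoy flashes, events per square
#'   micrometre per hour (default 0).
#' @param amplitude Peak amplitude of a focus above background, a.u.
#'   (default 200).
#' @param seed Integer seed.
#'
#' @return A `frap_spec` object.
#' @export
frap_spec <- function(true_rate, frame_interval = 5, duration = 600,
                      track_speed = 255, decoy_density = 0,
                      amplitude = 200, seed = NULL) {
  check_number(true_rate, "true_rate", min = 0)
  check_number(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  check_number(duration, "duration", min = frame_interval, strict_min = TRUE)
  check_number(track_speed, "track_speed", min = 0)
  check_number(decoy_density, "decoy_density", min = 0)
  check_number(amplitude, "amplitude", min = 0)
  structure(
    list(true_rate = true_rate, frame_interval = frame_interval,
         duration = duration, track_speed = track_speed,
         decoy_density = decoy_density, amplitude = amplitude, seed = seed),
    class = "frap_spec"
  )
}

# Pixel-centre coordinate conventions: pixel j covers ((j-1)*px, j*px] nm,
# centre at (j - 0.5) * px.
nm_to_px <- function(x_nm, pixel_size) x_nm / pixel_size + 0.5
px_to_nm <- function(j, pixel_size) (j - 0.5) * pixel_size

# Add an isotropic Gaussian spot (peak amplitude `amp`, sd `sigma_px`) to
# `img` at pixel-centre coordinates (cx, cy); separable outer-product stamp.
stamp_spot <- function(img, cx, cy, amp, sigma_px, halfwidth = ceiling(4 * sigma_px)) {
  nx <- ncol(img); ny <- nrow(img)
  x_lo <- max(1L, floor(cx - halfwidth)); x_hi <- min(nx, ceiling(cx + halfwidth))
  y_lo <- max(1L, floor(cy - halfwidth)); y_hi <- min(ny, ceiling(cy + halfwidth))
  if (x_lo > x_hi || y_lo > y_hi) return(img) # spot entirely outside
  jx <- x_lo:x_hi
  jy <- y_lo:y_hi
  gx <- exp(-(jx - cx)^2 / (2 * sigma_px^2))
  gy <- exp(-(jy - cy)^2 / (2 * sigma_px^2))
  img[jy, jx] <- img[jy, jx] + amp * (gy %o% gx)
  img
}

#' Generate a post-bleach FRAP movie with known insertion events
#'
#' Insertion times are drawn from a homogeneous Poisson process with
#' intensity `true_rate * field area`; positions are uniform over the field.
#' Each inserted focus appears at the first frame at or after its insertion
#' time, persists to the end of the movie, and translates in a random
#' direction at `track_speed`. Decoy flashes appear for exactly one frame.
#' Ground truth lists true insertions only.
#'
#' @param spec A [frap_spec()].
#' @param imaging An [imaging_params()]; `field_size` sets the bleached area.
#' @param render If `FALSE`, skip pixel rendering and return only the ground
#'   truth (fast path for statistical checks of the event process).
#'
#' @return A list with `movie` (array `ny x nx x n_frames`, or `NULL` when
#'   `render = FALSE`), `truth` (tibble: `event_id`, `time_s`, `x_um`,
#'   `y_um`, `direction_rad`, `first_frame`), `decoys` (same columns, the
#'   one-frame flashes), `n_frames`, and `frame_interval`.
#' @examples
#' sim <- generate_frap_movie(frap_spec(2, duration = 60, seed = 1),
#'                            imaging_params(), render = FALSE)
#' sim$truth
#' @export
generate_frap_movie <- function(spec, imaging = imaging_params(), render = TRUE) {
  stopifnot(inherits(spec, "frap_spec"), inherits(imaging, "imaging_params"))
  local_seed(spec$seed)
  px_um <- imaging$pixel_size / 1000
  nx <- floor(imaging$field_size[1] / px_um)
  ny <- floor(imaging$field_size[2] / px_um)
  w_um <- nx * px_um
  h_um <- ny * px_um
  area <- w_um * h_um
  n_frames <- as.integer(floor(spec$duration / spec$frame_interval)) + 1L
  dur_h <- spec$duration / 3600

  draw_events <- function(rate) {
    n <- rpois(1L, rate * area * dur_h)
    tibble(
      time_s = sort(runif(n, 0, spec$duration)),
      x_um = runif(n, 0, w_um),
      y_um = runif(n, 0, h_um),
      direction_rad = runif(n, 0, 2 * pi)
    )
  }

  truth <- draw_events(spec$true_rate)
  decoys <- draw_events(spec$decoy_density)
  # first frame at or after the insertion time; frame f is at (f-1)*dt
  first_frame <- function(t) pmin(n_frames, ceiling(t / spec$frame_interval) + 1L)
  truth$first_frame <- if (nrow(truth)) first_frame(truth$time_s) else integer()
  decoys$first_frame <- if (nrow(decoys)) first_frame(decoys$time_s) else integer()
  truth <- dplyr::bind_cols(tibble(event_id = seq_len(nrow(truth))), truth)
  decoys <- dplyr::bind_cols(tibble(event_id = seq_len(nrow(decoys))), decoys)

  movie <- NULL
  if (render) {
    sigma_px <- psf_sigma(imaging) / imaging$pixel_size
    speed_um_s <- spec$track_speed / 1000 / 60
    movie <- array(imaging$background, dim = c(ny, nx, n_frames))
    for (f in seq_len(n_frames)) {
      t_f <- (f - 1L) * spec$frame_interval
      frame <- movie[, , f]
      vis <- which(truth$first_frame <= f)
      for (i in vis) {
        dtime <- t_f - truth$time_s[i]
        cx <- nm_to_px((truth$x_um[i] + speed_um_s * dtime * cos(truth$direction_rad[i])) * 1000,
                       imaging$pixel_size)
        cy <- nm_to_px((truth$y_um[i] + speed_um_s * dtime * sin(truth$direction_rad[i])) * 1000,
                       imaging$pixel_size)
        frame <- stamp_spot(frame, cx, cy, spec$amplitude, sigma_px)
      }
      flash <- which(decoys$first_frame == f)
      for (i in flash) {
        frame <- stamp_spot(frame,
                            nm_to_px(decoys$x_um[i] * 1000, imaging$pixel_size),
                            nm_to_px(decoys$y_um[i] * 1000, imaging$pixel_size),
                            spec$amplitude, sigma_px)
      }
      movie[, , f] <- apply_noise(frame, imaging)
    }
  }

  list(movie = movie, truth = truth, decoys = decoys,
       n_frames = n_frames, frame_interval = spec$frame_interval,
       field_um = c(w_um, h_um))
}
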