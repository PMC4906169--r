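#' Named presets for the study conditions
#'
#' Returns a fully populated generator spec whose generative parameters equal
#' the population values reported for the wild-type (`wt_`) and *stl1stl2*
#' mutant (`stl_`) conditions: solid-Golgi fractions of 8% (n = 870) and 54%
#' (n = 820), plasma-membrane delivery rates of 4.8 and 2.2 foci per square
#' micrometre per hour, and migration speeds of 255 +/- 128 and 191 +/- 92
#' nm/min. Ring diameters for the Golgi presets are 800 +/- 150 nm; FRAP
#' presets use the 5-s interval / 10-min duration protocol with one-frame
#' decoy flashes; speed presets use 30-frame tracks with 50-nm localization
#' noise.
#'
#' @param name One of `"wt_golgi"`, `"stl_golgi"`, `"wt_frap"`,
#'   `"stl_frap"`, `"wt_speed"`, `"stl_speed"`.
#' @param seed Optional integer seed stored in the returned spec.
#'
#' @return A [golgi_population_spec()], [frap_spec()] or [track_spec()].
#' @examples
#' preset("stl_golgi")$solid_fraction # 0.54
#' preset("wt_frap")$true_rate        # 4.8
#' @export
preset <- function(name, seed = NULL) {
  valid <- c("wt_golgi", "stl_golgi", "wt_frap", "stl_frap",
             "wt_speed", "stl_speed")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    abort(sprintf("Unknown preset %s. Valid presets: %s.",
                  deparse(name), paste(valid, collapse = ", ")))
  }
  switch(name,
    wt_golgi = golgi_population_spec(
      n_objects = 870, solid_fraction = 0.08,
      ring_diameter_mean = 800, ring_diameter_sd = 150,
      ring_amplitude = 100, solid_amplitude = 100, seed = seed),
    stl_golgi = golgi_population_spec(
      n_objects = 820, solid_fraction = 0.54,
      ring_diameter_mean = 800, ring_diameter_sd = 150,
      ring_amplitude = 100, solid_amplitude = 100, seed = seed),
    wt_frap = frap_spec(
      true_rate = 4.8, frame_interval = 5, duration = 600,
      track_speed = 255, decoy_density = 1, seed = seed),
    stl_frap = frap_spec(
      true_rate = 2.2, frame_interval = 5, duration = 600,
      track_speed = 191, decoy_density = 1, seed = seed),
    wt_speed = track_spec(
      n_tracks = 500, speed_mean = 255, speed_sd = 128,
      n_frames = 30, frame_interval = 5, loc_noise_sd = 50, seed = seed),
    stl_speed = track_spec(
      n_tracks = 500, speed_mean = 191, speed_sd = 92,
      n_frames = 30, frame_interval = 5, loc_noise_sd = 50, seed = seed)
  )
}
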