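#' Run a configured analysis stage end to end
#'
#' Dispatches a validated [load_config()] configuration to one of the
#' pipeline stages, writes the stage outputs plus a provenance record to
#' `config$out_dir`, and returns the result bundle. Every output is
#' regenerable from the configuration, the inputs and the seed alone.
#'
#' Stages:
#' * `"simulate"` — run the generator named by `config$preset` (or a
#'   Golgi-population generator from explicit parameters) and write the
#'   synthetic data plus ground truth;
#' * `"classify"` — read a profiles CSV (`source_id`, `position_nm`,
#'   `intensity`), run [analyze_population()], write per-object and summary
#'   CSVs;
#' * `"frap"` — read a movie TIFF, run [detect_insertion_events()] and
#'   [delivery_rate()], write events and rate CSVs;
#' * `"track"` — read a detections CSV (`frame`, `x_nm`, `y_nm`) or a movie
#'   TIFF, link and compute speeds, write tracks and speeds CSVs;
#' * `"coloc"` — read two TIFFs, write Manders coefficients;
#' * `"gold"` — read a particles CSV, write relative distances and summary;
#' * `"compare"` — read two single-column CSVs, write the group comparison.
#'
#' @param config A `run_config` from [load_config()], or a path to a config
#'   file.
#' @return A list of class `result_bundle`: `stage`, `outputs` (named file
#'   paths), `tables` (the result tibbles) and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- c("simulate", "classify", "frap", "track", "coloc", "gold", "compare")
  if (is.null(config$stage) || !config$stage %in% stages) {
    abort(sprintf("Unknown or missing stage %s. Available stages: %s.",
                  deparse(config$stage), paste(stages, collapse = ", ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  imaging <- imaging_params(
    pixel_size = config$imaging$pixel_size, psf_fwhm = config$imaging$psf_fwhm,
    background = config$imaging$background,
    photon_scale = config$imaging$photon_scale,
    read_noise_sd = config$imaging$read_noise_sd,
    field_size = unlist(config$imaging$field_size)
  )
  say <- function(fmt, ...) {
    if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
  }
  say("stage %s -> %s", config$stage, config$out_dir)
  out_path <- function(name) file.path(config$out_dir, name)
  outputs <- list(); tables <- list()
  wrap_stage <- function(expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", config$stage, conditionMessage(e)))
    })
  }

  wrap_stage(switch(config$stage,
    simulate = {
      if (is.null(config$preset)) abort("`preset` is required for the simulate stage.")
      spec <- preset(config$preset, seed = config$seed)
      if (inherits(spec, "golgi_population_spec")) {
        sim <- generate_profile_population(spec, imaging)
        utils::write.csv(sim$profiles, outputs$profiles <- out_path("profiles.csv"),
                         row.names = FALSE)
        utils::write.csv(sim$truth, outputs$truth <- out_path("truth.csv"),
                         row.names = FALSE)
        tables <- list(profiles = sim$profiles, truth = sim$truth)
      } else if (inherits(spec, "frap_spec")) {
        sim <- generate_frap_movie(spec, imaging)
        write_image_stack(sim$movie, outputs$movie <- out_path("movie.tif"))
        utils::write.csv(sim$truth, outputs$truth <- out_path("truth.csv"),
                         row.names = FALSE)
        tables <- list(truth = sim$truth)
      } else {
        sim <- generate_track_set(spec, imaging)
        utils::write.csv(sim$detections, outputs$detections <- out_path("detections.csv"),
                         row.names = FALSE)
        utils::write.csv(sim$truth, outputs$truth <- out_path("truth.csv"),
                         row.names = FALSE)
        tables <- list(detections = sim$detections, truth = sim$truth)
      }
    },
    classify = {
      profiles <- read_table_csv(config$input, c("source_id", "position_nm", "intensity"))
      pop <- analyze_population(
        profiles,
        min_prominence_frac = config$profile$min_prominence_frac,
        min_separation_nm = config$profile$min_separation_nm,
        resolution_limit = config$profile$resolution_limit,
        width_definition = config$profile$width_definition
      )
      utils::write.csv(pop$objects, outputs$objects <- out_path("objects.csv"),
                       row.names = FALSE)
      utils::write.csv(pop$summary, outputs$summary <- out_path("summary.csv"),
                       row.names = FALSE)
      tables <- list(objects = pop$objects, summary = pop$summary)
    },
    frap = {
      movie <- read_image_stack(need_input(config$input))
      ev <- detect_insertion_events(
        movie, frame_interval_s = config$frap$frame_interval_s,
        pixel_size = config$imaging$pixel_size,
        r_excl_nm = config$frap$r_excl_nm, k_before = config$frap$k_before,
        k_after = config$frap$k_after, d_max_nm = config$frap$d_max_nm,
        margin_frac = config$frap$margin_frac, sigma_px = config$frap$sigma_px,
        threshold_frac = config$frap$threshold_frac
      )
      rate <- delivery_rate(ev)
      utils::write.csv(ev$events, outputs$events <- out_path("events.csv"),
                       row.names = FALSE)
      utils::write.csv(rate, outputs$rate <- out_path("rate.csv"), row.names = FALSE)
      tables <- list(events = ev$events, rate = rate)
    },
    track = {
      path <- need_input(config$input)
      detections <- if (grepl("\\.csv$", path)) {
        read_table_csv(path, c("frame", "x_nm", "y_nm"))
      } else {
        movie <- read_image_stack(path)
        purrr::map(seq_len(dim(movie)[3]), function(f) {
          d <- detect_foci(movie[, , f], sigma_px = config$track$sigma_px,
                           threshold_frac = config$track$threshold_frac,
                           pixel_size = config$imaging$pixel_size)
          dplyr::mutate(d, frame = f)
        }) |> purrr::list_rbind()
      }
      tracks <- link_trajectories(detections, d_max_nm = config$track$d_max_nm,
                                  max_gap = config$track$max_gap,
                                  min_track_len = config$track$min_track_len)
      speeds <- track_speeds(tracks, config$track$frame_interval_s,
                             method = config$track$method,
                             min_track_len = config$track$min_track_len)
      utils::write.csv(tracks, outputs$tracks <- out_path("tracks.csv"),
                       row.names = FALSE)
      utils::write.csv(speeds, outputs$speeds <- out_path("speeds.csv"),
                       row.names = FALSE)
      tables <- list(tracks = tracks, speeds = speeds)
    },
    coloc = {
      a <- read_image_stack(need_input(config$input))
      b <- read_image_stack(need_input(config$input_b, "input_b"))
      res <- manders(as_frame(a), as_frame(b),
                     threshold_a = config$coloc$threshold_a,
                     threshold_b = config$coloc$threshold_b)
      utils::write.csv(res, outputs$coloc <- out_path("coloc.csv"), row.names = FALSE)
      tables <- list(coloc = res)
    },
    gold = {
      particles <- read_table_csv(need_input(config$input), "position_nm")
      d <- gold_relative_distance(particles, axis_length = config$gold$axis_length %||%
                                    config$gold$golgi_length)
      summ <- summarize_distribution(d$d_rel)
      utils::write.csv(d, outputs$distances <- out_path("gold_distances.csv"),
                       row.names = FALSE)
      utils::write.csv(summ$stats, outputs$summary <- out_path("gold_summary.csv"),
                       row.names = FALSE)
      tables <- list(distances = d, summary = summ$stats)
    },
    compare = {
      a <- read_table_csv(need_input(config$input), "value")$value
      b <- read_table_csv(need_input(config$input_b, "input_b"), "value")$value
      res <- compare_groups(a, b)
      utils::write.csv(res, outputs$comparison <- out_path("comparison.csv"),
                       row.names = FALSE)
      tables <- list(comparison = res)
    }
  ))

  provenance <- list(
    package = "golgiring",
    version = as.character(utils::packageVersion("golgiring")),
    stage = config$stage, seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config)
  )
  jsonlite::write_json(provenance, out_path("provenance.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  outputs$provenance <- out_path("provenance.json")
  structure(list(stage = config$stage, outputs = outputs, tables = tables,
                 provenance = provenance),
            class = "result_bundle")
}

need_input <- function(path, field = "input") {
  if (is.null(path)) abort(sprintf("`%s` path is required for this stage.", field))
  path
}

read_table_csv <- function(path, required_cols) {
  path <- need_input(path)
  if (!file.exists(path)) abort(sprintf("No such file: '%s'.", path))
  x <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(required_cols, names(x))
  if (length(missing)) {
    abort(sprintf("'%s' lacks required column(s): %s.", path,
                  paste(missing, collapse = ", ")))
  }
  x
}

as_frame <- function(x) if (is.matrix(x)) x else x[, , 1]

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle: stage '%s'>\n", x$stage))
  for (nm in names(x$outputs)) cat(sprintf("  %s: %s\n", nm, x$outputs[[nm]]))
  invisible(x)
}
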