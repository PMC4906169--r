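#' Score plasma-membrane insertion events in a post-bleach movie
#'
#' A focus detection at frame `t` is scored as an insertion event when
#' (i) no detection lay within `r_excl_nm` of its position in any of the
#' `k_before` preceding frames (the immediate region must be devoid of
#' particles before delivery), and (ii) the particle can be followed for at
#' least `k_after` subsequent consecutive frames with per-step displacement
#' at most `d_max_nm` (the characteristic post-insertion tracking
#' behaviour). Events are only scored inside the central subregion (the
#' movie cropped by `margin_frac` per side) to exclude particles drifting in
#' from outside the bleached area, and only at frames where both criteria
#' can be evaluated (`k_before < t <= n_frames - k_after`).
#'
#' Because delivered foci persist, the neighbourhood criterion progressively
#' masks part of the field: the function therefore also reports the
#' *effective* scorable exposure, `sum_t A_eff(t) * dt`, where `A_eff(t)` is
#' the central-subregion area not within `r_excl_nm` of any detection in the
#' `k_before` frames preceding `t`. Using the effective exposure in
#' [delivery_rate()] keeps the estimator unbiased as the field fills up.
#'
#' @param movie 3-D array (`ny x nx x n_frames`).
#' @param frame_interval_s Frame interval in seconds.
#' @param pixel_size Pixel size in nm (default 133).
#' @param r_excl_nm Exclusion radius for the devoid-neighbourhood criterion,
#'   nm (default 500).
#' @param k_before Preceding frames that must be devoid (default 2).
#' @param k_after Subsequent frames the particle must persist (default 4).
#' @param d_max_nm Maximum per-step displacement when following the particle,
#'   nm (default 400).
#' @param margin_frac Fractional margin cropped from each side to define the
#'   central subregion (default 0.2).
#' @param sigma_px,threshold_frac Focus detection settings; the detection
#'   threshold is `threshold_frac` times the maximum Laplacian-of-Gaussian
#'   response over the whole movie, so sensitivity is uniform across frames
#'   (defaults 1.7 and 0.2).
#'
#' @return A list of class `insertion_events` with
#'   * `events`: tibble `x_um`, `y_um`, `frame`, `time_s`, `persistence`;
#'   * `area_um2`: geometric central-subregion area;
#'   * `effective_area_um2`: mean unmasked central area over scorable frames;
#'   * `duration_scored_s`: scorable observation time;
#'   * `exposure_um2_h`: `effective_area_um2 * duration_scored_s / 3600`.
#' @examples
#' sim <- generate_frap_movie(frap_spec(3, duration = 120, seed = 1),
#'                            imaging_params(field_size = c(10, 10)))
#' ev <- detect_insertion_events(sim$movie, sim$frame_interval)
#' nrow(ev$events)
#' @export
detect_insertion_events <- function(movie, frame_interval_s, pixel_size = 133,
                                    r_excl_nm = 500, k_before = 2, k_after = 4,
                                    d_max_nm = 400, margin_frac = 0.2,
                                    sigma_px = 1.7, threshold_frac = 0.2) {
  stopifnot(is.array(movie), length(dim(movie)) == 3L)
  check_number(frame_interval_s, "frame_interval_s", min = 0, strict_min = TRUE)
  k_before <- check_count(k_before, "k_before", min = 1L)
  k_after <- check_count(k_after, "k_after", min = 1L)
  ny <- dim(movie)[1]; nx <- dim(movie)[2]; nf <- dim(movie)[3]
  if (nf < k_before + k_after + 1L) {
    abort(sprintf("Movie has %d frames; need at least k_before + k_after + 1 = %d.",
                  nf, k_before + k_after + 1L))
  }

  # per-frame detections at a movie-wide absolute threshold
  resp_max <- 0
  responses <- vector("list", nf)
  for (f in seq_len(nf)) {
    responses[[f]] <- log_response(movie[, , f], sigma_px)
    resp_max <- max(resp_max, max(responses[[f]]))
  }
  thr <- threshold_frac * resp_max
  dets <- purrr::map(seq_len(nf), function(f) {
    pk <- local_maxima_2d(responses[[f]], thr)
    if (nrow(pk) == 0L) {
      return(tibble(frame = integer(), x_nm = numeric(), y_nm = numeric()))
    }
    tibble(frame = f, x_nm = px_to_nm(pk$x, pixel_size),
           y_nm = px_to_nm(pk$y, pixel_size))
  })
  rm(responses)

  # central subregion bounds in nm
  w_nm <- nx * pixel_size; h_nm <- ny * pixel_size
  cx0 <- margin_frac * w_nm; cx1 <- (1 - margin_frac) * w_nm
  cy0 <- margin_frac * h_nm; cy1 <- (1 - margin_frac) * h_nm
  area_um2 <- (cx1 - cx0) * (cy1 - cy0) / 1e6

  scorable <- seq(k_before + 1L, nf - k_after)
  events <- list()
  occluded_frac <- numeric(length(scorable))

  # occlusion grid over the central subregion, at pixel resolution
  gx <- px_to_nm(seq_len(nx), pixel_size)
  gy <- px_to_nm(seq_len(ny), pixel_size)
  in_cx <- gx >= cx0 & gx <= cx1
  in_cy <- gy >= cy0 & gy <= cy1
  n_central_px <- sum(in_cx) * sum(in_cy)
  r_px <- r_excl_nm / pixel_size
  disc_dx <- seq(-ceiling(r_px), ceiling(r_px))
  disc <- outer(disc_dx, disc_dx, function(a, b) a^2 + b^2 <= r_px^2)

  for (si in seq_along(scorable)) {
    f <- scorable[si]
    prev <- dplyr::bind_rows(dets[seq(f - k_before, f - 1L)])
    # occluded-area fraction of the central subregion at this frame
    mask <- matrix(FALSE, ny, nx)
    if (nrow(prev)) {
      pj <- round(nm_to_px(prev$x_nm, pixel_size))
      pi_ <- round(nm_to_px(prev$y_nm, pixel_size))
      for (q in seq_len(nrow(prev))) {
        jr <- pj[q] + disc_dx; ir <- pi_[q] + disc_dx
        jok <- jr >= 1L & jr <= nx; iok <- ir >= 1L & ir <= ny
        mask[ir[iok], jr[jok]] <- mask[ir[iok], jr[jok]] | disc[iok, jok]
      }
    }
    occluded_frac[si] <- if (n_central_px) sum(mask[in_cy, in_cx]) / n_central_px else 0

    cur <- dets[[f]]
    if (nrow(cur) == 0L) next
    central <- cur$x_nm >= cx0 & cur$x_nm <= cx1 & cur$y_nm >= cy0 & cur$y_nm <= cy1
    for (d in which(central)) {
      # (i) devoid neighbourhood in the preceding k_before frames
      if (nrow(prev) &&
          min((prev$x_nm - cur$x_nm[d])^2 + (prev$y_nm - cur$y_nm[d])^2) <= r_excl_nm^2) {
        next
      }
      # (ii) persistence: follow nearest detection forward k_after frames
      pos <- c(cur$x_nm[d], cur$y_nm[d])
      persist <- 0L
      for (s in seq_len(nf - f)) {
        nxt <- dets[[f + s]]
        if (nrow(nxt) == 0L) break
        dd <- (nxt$x_nm - pos[1])^2 + (nxt$y_nm - pos[2])^2
        jbest <- which.min(dd)
        if (dd[jbest] > d_max_nm^2) break
        pos <- c(nxt$x_nm[jbest], nxt$y_nm[jbest])
        persist <- persist + 1L
      }
      if (persist >= k_after) {
        events[[length(events) + 1L]] <- tibble(
          x_um = cur$x_nm[d] / 1000, y_um = cur$y_nm[d] / 1000,
          frame = f, time_s = (f - 1L) * frame_interval_s,
          persistence = persist
        )
      }
    }
  }

  events <- if (length(events)) purrr::list_rbind(events) else {
    tibble(x_um = numeric(), y_um = numeric(), frame = integer(),
           time_s = numeric(), persistence = integer())
  }
  duration_scored_s <- length(scorable) * frame_interval_s
  effective_area_um2 <- area_um2 * (1 - mean(occluded_frac))
  structure(
    list(events = events, area_um2 = area_um2,
         effective_area_um2 = effective_area_um2,
         duration_scored_s = duration_scored_s,
         exposure_um2_h = effective_area_um2 * duration_scored_s / 3600),
    class = "insertion_events"
  )
}

#' @export
print.insertion_events <- function(x, ...) {
  cat(sprintf("<insertion_events: %d events>\n", nrow(x$events)))
  cat(sprintf("  central subregion %.1f um^2 (effective %.1f um^2 after neighbourhood masking)\n",
              x$area_um2, x$effective_area_um2))
  cat(sprintf("  scorable duration %.0f s | exposure %.2f um^2 h\n",
              x$duration_scored_s, x$exposure_um2_h))
  invisible(x)
}

#' Convert an event count to a delivery rate
#'
#' `rate = n_events / (area * duration_in_hours)`, in events per square
#' micrometre per hour.
#'
#' @param events An `insertion_events` object, an event table, or an event
#'   count.
#' @param area_um2 Scored membrane area in square micrometres. For an
#'   `insertion_events` input this defaults to its occlusion-corrected
#'   `effective_area_um2`.
#' @param duration_s Scored duration in seconds; defaults to the
#'   `insertion_events` object's `duration_scored_s`.
#'
#' @return One-row tibble: `n_events`, `area_um2`, `duration_h`,
#'   `rate_per_um2_h`.
#' @examples
#' delivery_rate(12, area_um2 = 25, duration_s = 1800) # 0.96
#' @export
delivery_rate <- function(events, area_um2 = NULL, duration_s = NULL) {
  if (inherits(events, "insertion_events")) {
    area_um2 <- area_um2 %||% events$effective_area_um2
    duration_s <- duration_s %||% events$duration_scored_s
    n <- nrow(events$events)
  } else if (is.data.frame(events)) {
    n <- nrow(events)
  } else {
    n <- check_count(events, "events", min = 0L)
  }
  check_number(area_um2, "area_um2", min = 0, strict_min = TRUE)
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  duration_h <- duration_s / 3600
  tibble(n_events = n, area_um2 = area_um2, duration_h = duration_h,
         rate_per_um2_h = n / (area_um2 * duration_h))
}
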