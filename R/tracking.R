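#' Detect fluorescent foci in a single frame
#'
#' Blob detection by (negative) Laplacian-of-Gaussian filtering at scale
#' `sigma_px`: local maxima of the LoG response above a threshold are
#' reported with sub-pixel positions from quadratic interpolation of the
#' response peak in x and y.
#'
#' @param frame Numeric matrix (rows = y, cols = x).
#' @param sigma_px LoG scale in pixels; match to the PSF sigma
#'   (default 1.7, i.e. a 266-nm-FWHM PSF at 133 nm/px, scaled slightly up).
#' @param threshold_frac Threshold as a fraction of the maximum LoG response
#'   in this frame (default 0.3). Ignored when `threshold_abs` is given.
#' @param threshold_abs Absolute response threshold; use when detecting
#'   across movie frames with a common sensitivity.
#' @param pixel_size Pixel size in nm (default 133).
#'
#' @return Tibble: `x_px`, `y_px`, `x_nm`, `y_nm`, `intensity` (raw frame
#'   value at the peak pixel), `response` (LoG response). Zero rows when
#'   nothing exceeds the threshold.
#' @examples
#' img <- matrix(0, 32, 32)
#' img[14:18, 14:18] <- 50 * dnorm(-2:2) %o% dnorm(-2:2) / dnorm(0)^2
#' detect_foci(img, sigma_px = 1.5)
#' @export
detect_foci <- function(frame, sigma_px = 1.7, threshold_frac = 0.3,
                        threshold_abs = NULL, pixel_size = 133) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  resp <- log_response(frame, sigma_px)
  thr <- threshold_abs %||% (threshold_frac * max(resp))
  peaks_xy <- local_maxima_2d(resp, thr)
  if (nrow(peaks_xy) == 0L) {
    return(tibble(x_px = numeric(), y_px = numeric(), x_nm = numeric(),
                  y_nm = numeric(), intensity = numeric(), response = numeric()))
  }
  # sub-pixel refinement: 1D quadratic through the 3-point neighbourhood
  refine <- function(a, b, c) {
    den <- a - 2 * b + c
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (a - c) / den))
  }
  dx <- vapply(seq_len(nrow(peaks_xy)), function(k) {
    i <- peaks_xy$y[k]; j <- peaks_xy$x[k]
    refine(resp[i, j - 1L], resp[i, j], resp[i, j + 1L])
  }, numeric(1))
  dy <- vapply(seq_len(nrow(peaks_xy)), function(k) {
    i <- peaks_xy$y[k]; j <- peaks_xy$x[k]
    refine(resp[i - 1L, j], resp[i, j], resp[i + 1L, j])
  }, numeric(1))
  x_px <- peaks_xy$x + dx
  y_px <- peaks_xy$y + dy
  tibble(
    x_px = x_px, y_px = y_px,
    x_nm = px_to_nm(x_px, pixel_size), y_nm = px_to_nm(y_px, pixel_size),
    intensity = frame[cbind(peaks_xy$y, peaks_xy$x)],
    response = resp[cbind(peaks_xy$y, peaks_xy$x)]
  )
}

# Negative-LoG filter response (bright blobs -> positive peaks),
# scale-normalized by sigma^2.
log_response <- function(frame, sigma_px) {
  half <- max(2L, ceiling(4 * sigma_px))
  ax <- seq(-half, half)
  g <- exp(-ax^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  # LoG kernel = sum of separable second-derivative terms; build 2D directly
  xx <- matrix(ax, 2 * half + 1, 2 * half + 1)
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  k <- -(r2 - 2 * sigma_px^2) / sigma_px^2 * exp(-r2 / (2 * sigma_px^2))
  k <- k - mean(k) # zero-DC so flat background gives zero response
  as.matrix(EBImage::filter2(EBImage::Image(frame), k))
}

# Strict interior local maxima (8-neighbourhood) above `thr`.
local_maxima_2d <- function(resp, thr) {
  ny <- nrow(resp); nx <- ncol(resp)
  core <- resp[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > thr &
    core >= resp[1:(ny - 2), 2:(nx - 1)] & core >= resp[3:ny, 2:(nx - 1)] &
    core >= resp[2:(ny - 1), 1:(nx - 2)] & core >= resp[2:(ny - 1), 3:nx] &
    core >= resp[1:(ny - 2), 1:(nx - 2)] & core >= resp[1:(ny - 2), 3:nx] &
    core >= resp[3:ny, 1:(nx - 2)] & core >= resp[3:ny, 3:nx]
  idx <- which(is_max, arr.ind = TRUE)
  tibble(y = as.integer(idx[, 1] + 1L), x = as.integer(idx[, 2] + 1L))
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame assignment: candidate links
#' between open tracks and current-frame detections are sorted by distance
#' (ties broken by lower track id) and accepted while both ends are free and
#' the step is at most `d_max_nm`. Tracks may skip up to `max_gap` frames;
#' unmatched detections seed new tracks; tracks shorter than
#' `min_track_len` detections are discarded.
#'
#' @param detections Tibble with columns `frame`, `x_nm`, `y_nm` (sorted or
#'   not; sorted internally by frame).
#' @param d_max_nm Maximum per-step displacement in nm (default 400).
#' @param max_gap Maximum number of skipped frames within a track
#'   (default 1).
#' @param min_track_len Minimum detections per reported track (default 5).
#'
#' @return Tibble `track_id`, `frame`, `x_nm`, `y_nm` plus any other
#'   detection columns, ordered by track then frame.
#' @examples
#' det <- generate_track_set(track_spec(2, 255, 0, seed = 1))$detections
#' tracks <- link_trajectories(det)
#' dplyr::count(tracks, track_id)
#' @export
link_trajectories <- function(detections, d_max_nm = 400, max_gap = 1,
                              min_track_len = 5) {
  stopifnot(all(c("frame", "x_nm", "y_nm") %in% names(detections)))
  det <- dplyr::arrange(as_tibble(detections), .data$frame)
  det$.track <- NA_integer_
  frames <- sort(unique(det$frame))
  # open track registry: id, last x/y, last frame
  open_id <- integer(); open_x <- numeric(); open_y <- numeric(); open_f <- numeric()
  next_id <- 1L
  for (f in frames) {
    rows <- which(det$frame == f)
    alive <- which(f - open_f <= max_gap + 1)
    if (length(alive) && length(rows)) {
      dx <- outer(open_x[alive], det$x_nm[rows], "-")
      dy <- outer(open_y[alive], det$y_nm[rows], "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= d_max_nm, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dist[cand], open_id[alive][cand[, 1]])
        used_t <- logical(length(alive)); used_d <- logical(length(rows))
        for (k in ord) {
          ti <- cand[k, 1]; di <- cand[k, 2]
          if (!used_t[ti] && !used_d[di]) {
            used_t[ti] <- TRUE; used_d[di] <- TRUE
            id <- open_id[alive[ti]]
            det$.track[rows[di]] <- id
            open_x[alive[ti]] <- det$x_nm[rows[di]]
            open_y[alive[ti]] <- det$y_nm[rows[di]]
            open_f[alive[ti]] <- f
          }
        }
      }
    }
    # unmatched detections start new tracks
    new_rows <- rows[is.na(det$.track[rows])]
    if (length(new_rows)) {
      ids <- seq.int(next_id, length.out = length(new_rows))
      det$.track[new_rows] <- ids
      open_id <- c(open_id, ids)
      open_x <- c(open_x, det$x_nm[new_rows])
      open_y <- c(open_y, det$y_nm[new_rows])
      open_f <- c(open_f, rep(f, length(new_rows)))
      next_id <- next_id + length(new_rows)
    }
    # drop tracks that exceeded the gap allowance
    keep <- f - open_f <= max_gap + 1
    open_id <- open_id[keep]; open_x <- open_x[keep]
    open_y <- open_y[keep]; open_f <- open_f[keep]
  }
  det |>
    dplyr::rename(track_id = ".track") |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter(dplyr::n() >= min_track_len) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::select("track_id", dplyr::everything())
}

#' Migration speed of a single trajectory
#'
#' `method = "slope"` (default) projects positions onto the track's
#' principal axis and takes the absolute slope of a least-squares regression
#' of projected position on time — robust to isotropic localization noise.
#' `method = "stepwise"` averages frame-to-frame displacements, which is
#' biased upward by localization noise and is provided for comparison.
#'
#' @param traj Tibble with columns `frame`, `x_nm`, `y_nm` for one track.
#' @param frame_interval_s Frame interval in seconds.
#' @param method `"slope"` or `"stepwise"`.
#' @param min_track_len Minimum detections required (default 5).
#'
#' @return One-row tibble: `speed_nm_min`, `method`, `n_frames`.
#' @examples
#' traj <- tibble::tibble(frame = 1:10, x_nm = 50 * (0:9), y_nm = 0)
#' trajectory_speed(traj, 5) # 600 nm/min
#' @export
trajectory_speed <- function(traj, frame_interval_s,
                             method = c("slope", "stepwise"),
                             min_track_len = 5) {
  method <- match.arg(method)
  stopifnot(all(c("frame", "x_nm", "y_nm") %in% names(traj)))
  check_number(frame_interval_s, "frame_interval_s", min = 0, strict_min = TRUE)
  traj <- dplyr::arrange(as_tibble(traj), .data$frame)
  n <- nrow(traj)
  if (n < min_track_len) {
    abort(sprintf("Track has %d detections; need at least %d.", n, min_track_len))
  }
  t_s <- (traj$frame - traj$frame[1]) * frame_interval_s
  if (method == "slope") {
    xy <- cbind(traj$x_nm - mean(traj$x_nm), traj$y_nm - mean(traj$y_nm))
    ev <- eigen(crossprod(xy) / n, symmetric = TRUE)$vectors[, 1]
    s <- xy %*% ev
    slope <- sum((t_s - mean(t_s)) * (s - mean(s))) / sum((t_s - mean(t_s))^2)
    speed <- abs(slope) * 60
  } else {
    steps <- sqrt(diff(traj$x_nm)^2 + diff(traj$y_nm)^2)
    dt <- diff(t_s)
    speed <- mean(steps / dt) * 60
  }
  tibble(speed_nm_min = speed, method = method, n_frames = n)
}

#' Speeds for every track in a linked table
#'
#' @param tracks Tibble from [link_trajectories()] (columns `track_id`,
#'   `frame`, `x_nm`, `y_nm`).
#' @inheritParams trajectory_speed
#' @return Tibble: `track_id`, `speed_nm_min`, `method`, `n_frames`.
#' @export
track_speeds <- function(tracks, frame_interval_s,
                         method = c("slope", "stepwise"), min_track_len = 5) {
  method <- match.arg(method)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter(dplyr::n() >= min_track_len) |>
    dplyr::group_modify(~ trajectory_speed(.x, frame_interval_s, method,
                                           min_track_len)) |>
    dplyr::ungroup()
}

#' Per-pixel time average of a movie
#'
#' @param movie 3-D array (`ny x nx x n_frames`) or a matrix (returned
#'   unchanged).
#' @return Matrix of per-pixel means.
#' @examples
#' m <- array(1:8, c(2, 2, 2)); time_average(m)
#' @export
time_average <- function(movie) {
  if (is.matrix(movie)) return(movie)
  stopifnot(is.array(movie), length(dim(movie)) == 3L)
  rowMeans(movie, dims = 2L)
}
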