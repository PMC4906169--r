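#' @describeIn fit_double_gaussian Plot the profile with the fitted
#'   double-Gaussian curve and component centres.
#' @param object A `double_gaussian_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.double_gaussian_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(
    position_nm = seq(min(dat$position_nm), max(dat$position_nm), length.out = 400)
  )
  grid$intensity <- profile_model(grid$position_nm, object$baseline,
                                  object$A1, object$mu1, object$sigma1,
                                  object$A2, object$mu2, object$sigma2)
  ggplot(dat, aes(x = .data$position_nm, y = .data$intensity)) +
    geom_point(colour = "grey40", size = 1) +
    geom_line(data = grid, colour = "black") +
    ggplot2::geom_vline(xintercept = c(object$mu1, object$mu2),
                        linetype = "dotted") +
    labs(x = "position (nm)", y = "intensity (a.u.)",
         title = sprintf("Double-Gaussian fit (%s mode), separation %.0f nm",
                         object$mode, object$mu2 - object$mu1)) +
    theme_minimal()
}

#' @describeIn analyze_population Diameter distribution by class with the
#'   ring/solid/rejected counts.
#' @param object A `golgi_population`.
#' @exportS3Method ggplot2::autoplot
autoplot.golgi_population <- function(object, ...) {
  dat <- dplyr::filter(object$objects, !is.na(.data$diameter_nm))
  ggplot(dat, aes(x = .data$class, y = .data$diameter_nm)) +
    geom_boxplot(outlier.size = 0.6) +
    labs(x = NULL, y = "object diameter (nm)",
         title = sprintf("ring %d / solid %d / rejected %d",
                         object$summary$n_ring, object$summary$n_solid,
                         object$summary$n_rejected)) +
    theme_minimal()
}

#' @describeIn gold_relative_distance Violin plot of the relative-distance
#'   distribution with the median marked.
#' @param object A `gold_distribution`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.gold_distribution <- function(object, ...) {
  dat <- tibble(d_rel = object$d_rel, group = "particles")
  ggplot(dat, aes(x = .data$group, y = .data$d_rel)) +
    geom_violin(fill = "grey85") +
    geom_point(data = tibble(group = "particles", d_rel = median(object$d_rel)),
               shape = 21, fill = "white", size = 3) +
    labs(x = NULL, y = "relative distance from Golgi centre") +
    ggplot2::ylim(0, 0.5) +
    theme_minimal()
}

#' Plot linked trajectories in the image plane
#'
#' @param tracks Tibble from [link_trajectories()].
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks) {
  stopifnot(all(c("track_id", "x_nm", "y_nm") %in% names(tracks)))
  ggplot(tracks, aes(x = .data$x_nm / 1000, y = .data$y_nm / 1000,
                     group = .data$track_id)) +
    geom_line(alpha = 0.6) +
    labs(x = "x (um)", y = "y (um)") +
    ggplot2::coord_equal() +
    theme_minimal()
}
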