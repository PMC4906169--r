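#' Relative distance of gold particles from the Golgi centre
#'
#' The immuno-gold periphery statistic: each particle is projected onto the
#' Golgi long axis and its distance from the axis midpoint is divided by the
#' total axis length, giving a value in \[0, 0.5\] (0 = centre,
#' 0.5 = either end).
#'
#' Input geometry, one of:
#' * 1-D: `particles` has a `position_nm` column (axial positions) and
#'   `axis_length` gives the Golgi length — the form produced by
#'   [generate_gold_particles()];
#' * 2-D: `particles` has `x_nm`, `y_nm` columns and either `axis` (a 2x2
#'   matrix of endpoint rows) or `outline` (a polygon tibble with `x_nm`,
#'   `y_nm`) whose principal axis and projection extremes define the axis.
#'
#' @param particles Particle table (see above).
#' @param axis Optional 2x2 numeric matrix; rows are the axis endpoints
#'   (x_nm, y_nm).
#' @param outline Optional outline polygon tibble with `x_nm`, `y_nm`.
#' @param axis_length Axis length in nm for the 1-D form.
#' @param tol Particles projecting within `tol * L` outside the axis are
#'   clipped to the ends; beyond that an out-of-bounds error is raised
#'   (default 0.05).
#'
#' @return A tibble of class `gold_distribution`: `particle_id`, `s_rel`
#'   (projected position along the axis in \[0, 1\]) and `d_rel`
#'   (relative distance from the centre, in \[0, 0.5\]); the axis used is
#'   attached as attribute `"axis"`.
#' @examples
#' g <- generate_gold_particles(100, 1200, "uniform", seed = 1)
#' d <- gold_relative_distance(g, axis_length = 1200)
#' mean(d$d_rel)
#' @export
gold_relative_distance <- function(particles, axis = NULL, outline = NULL,
                                   axis_length = NULL, tol = 0.05) {
  stopifnot(is.data.frame(particles), nrow(particles) >= 1L)
  if ("position_nm" %in% names(particles)) {
    if (is.null(axis_length)) {
      abort("Provide `axis_length` with 1-D `position_nm` input.")
    }
    check_number(axis_length, "axis_length", min = 0, strict_min = TRUE)
    s <- particles$position_nm
    L <- axis_length
    ax <- matrix(c(0, 0, L, 0), 2, 2, byrow = TRUE)
  } else {
    if (!all(c("x_nm", "y_nm") %in% names(particles))) {
      abort("`particles` needs `position_nm` or `x_nm`/`y_nm` columns.")
    }
    if (is.null(axis) && !is.null(outline)) {
      axis <- outline_axis(outline)
    }
    if (is.null(axis)) abort("Provide `axis` endpoints or an `outline`.")
    axis <- as.matrix(axis)
    stopifnot(all(dim(axis) == c(2L, 2L)))
    v <- axis[2, ] - axis[1, ]
    L <- sqrt(sum(v^2))
    if (L <= 0) abort("Axis length must be positive.")
    u <- v / L
    s <- (particles$x_nm - axis[1, 1]) * u[1] + (particles$y_nm - axis[1, 2]) * u[2]
    ax <- axis
  }
  s_rel <- s / L
  if (any(s_rel < -tol | s_rel > 1 + tol)) {
    abort(sprintf(
      "%d particle(s) project outside the axis by more than %g%% of its length; check the outline/axis.",
      sum(s_rel < -tol | s_rel > 1 + tol), 100 * tol))
  }
  s_rel <- pmin(pmax(s_rel, 0), 1)
  out <- tibble(
    particle_id = if ("particle_id" %in% names(particles)) {
      particles$particle_id
    } else seq_len(nrow(particles)),
    s_rel = s_rel,
    d_rel = abs(s_rel - 0.5)
  )
  attr(out, "axis") <- ax
  class(out) <- c("gold_distribution", class(out))
  out
}

# Principal axis of an outline polygon: endpoints are the extreme
# projections of the vertices onto the first principal component.
outline_axis <- function(outline) {
  stopifnot(all(c("x_nm", "y_nm") %in% names(outline)), nrow(outline) >= 2L)
  xy <- cbind(outline$x_nm, outline$y_nm)
  ctr <- colMeans(xy)
  xyc <- sweep(xy, 2, ctr)
  u <- eigen(crossprod(xyc) / nrow(xyc), symmetric = TRUE)$vectors[, 1]
  s <- xyc %*% u
  rbind(ctr + min(s) * u, ctr + max(s) * u)
}

#' Summarize a distribution for violin/box display
#'
#' Median, quartiles (type-7 linear interpolation), 1.5 x IQR whisker
#' bounds, and a kernel density estimate over the data range.
#'
#' @param values Numeric vector, n >= 1.
#' @return A list of class `distribution_summary` with `stats` (one-row
#'   tibble: `n`, `median`, `q25`, `q75`, `whisker_lo`, `whisker_hi`,
#'   `degenerate`) and `density` (a [stats::density()] object, `NULL` when
#'   all values are equal), plus the data.
#' @examples
#' summarize_distribution(c(0.1, 0.2, 0.3))$stats
#' @export
summarize_distribution <- function(values) {
  if (!is.numeric(values) || sum(is.finite(values)) < 1L) {
    abort("`values` must contain at least one finite number.")
  }
  values <- values[is.finite(values)]
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  degenerate <- length(unique(values)) == 1L
  dens <- if (!degenerate && length(values) >= 2L) {
    density(values, from = min(values), to = max(values))
  } else NULL
  structure(
    list(
      stats = tibble(n = length(values), median = q[2], q25 = q[1], q75 = q[3],
                     whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr,
                     degenerate = degenerate),
      density = dens,
      values = values
    ),
    class = "distribution_summary"
  )
}

#' @export
print.distribution_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<distribution_summary: n = %d>\n", s$n))
  cat(sprintf("  median %.4g [Q1 %.4g, Q3 %.4g]%s\n", s$median, s$q25, s$q75,
              if (s$degenerate) " (degenerate: all values equal)" else ""))
  invisible(x)
}
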