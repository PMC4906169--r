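#' Classify and measure a population of Golgi cross-section profiles
#'
#' Runs the full morphometry chain on each profile: peak finding,
#' ring/solid/rejected classification, double-Gaussian fitting (free
#' separation for rings, separation fixed at the resolution limit for
#' solids), and the object-diameter statistic. Population fractions are
#' computed over classified (non-rejected) objects, matching how scored
#' Golgi percentages are reported.
#'
#' @param profiles Long tibble with columns `source_id`, `position_nm`,
#'   `intensity` (one block per object), e.g. from
#'   [generate_profile_population()].
#' @param min_prominence_frac,min_separation_nm Peak-finding settings, see
#'   [find_profile_peaks()].
#' @param resolution_limit Fixed separation for solid-mode fits, nm
#'   (default 266).
#' @param width_definition Passed to [object_diameter()].
#'
#' @return A `golgi_population` object with
#'   * `objects`: per-object tibble (`source_id`, `n_peaks`, `class`,
#'     `separation_nm`, `w1_nm`, `w2_nm`, `diameter_nm`, `converged`), and
#'   * `summary`: one-row tibble (`n_total`, `n_ring`, `n_solid`,
#'     `n_rejected`, `fraction_solid`, `fraction_ring`, `mean_diameter_nm`,
#'     `median_diameter_nm`, `sd_diameter_nm`).
#'   [tidy()] returns `objects`, [glance()] returns `summary`.
#' @examples
#' sim <- generate_profile_population(
#'   golgi_population_spec(20, solid_fraction = 0.5, seed = 1))
#' pop <- analyze_population(sim$profiles)
#' glance(pop)
#' @export
analyze_population <- function(profiles, min_prominence_frac = 0.2,
                               min_separation_nm = 200,
                               resolution_limit = 266,
                               width_definition = c("fwhm", "two_sigma")) {
  width_definition <- match.arg(width_definition)
  if (!is.data.frame(profiles) ||
      !all(c("source_id", "position_nm", "intensity") %in% names(profiles))) {
    abort("`profiles` must have columns `source_id`, `position_nm`, `intensity`.")
  }
  if (nrow(profiles) == 0L) abort("Need at least one profile.")

  ids <- unique(profiles$source_id)
  split_profiles <- split(profiles, factor(profiles$source_id, levels = ids))
  objects <- purrr::imap(split_profiles, function(prof, id) {
    peaks <- find_profile_peaks(prof, min_prominence_frac, min_separation_nm)
    cls <- classify_profile(peaks)
    row <- tibble(source_id = id, n_peaks = nrow(peaks), class = cls,
                  separation_nm = NA_real_, w1_nm = NA_real_, w2_nm = NA_real_,
                  diameter_nm = NA_real_, converged = NA)
    if (cls != "rejected") {
      fit <- fit_double_gaussian(
        prof, mode = if (cls == "ring") "free" else "fixed",
        R = resolution_limit, peaks = peaks)
      row$converged <- fit$converged
      if (fit$converged) {
        d <- object_diameter(fit, width_definition)
        row$separation_nm <- d$separation_nm
        row$w1_nm <- d$w1_nm
        row$w2_nm <- d$w2_nm
        row$diameter_nm <- d$diameter_nm
      }
    }
    row
  }) |> purrr::list_rbind()

  n_ring <- sum(objects$class == "ring")
  n_solid <- sum(objects$class == "solid")
  n_rejected <- sum(objects$class == "rejected")
  n_classified <- n_ring + n_solid
  if (n_classified == 0L) {
    warn("All profiles were rejected; population fractions are undefined.")
  }
  diam <- objects$diameter_nm[!is.na(objects$diameter_nm)]
  summary <- tibble(
    n_total = nrow(objects), n_ring = n_ring, n_solid = n_solid,
    n_rejected = n_rejected,
    fraction_solid = if (n_classified) n_solid / n_classified else NA_real_,
    fraction_ring = if (n_classified) n_ring / n_classified else NA_real_,
    mean_diameter_nm = if (length(diam)) mean(diam) else NA_real_,
    median_diameter_nm = if (length(diam)) median(diam) else NA_real_,
    sd_diameter_nm = if (length(diam) > 1) sd(diam) else NA_real_
  )
  structure(list(objects = objects, summary = summary,
                 width_definition = width_definition,
                 resolution_limit = resolution_limit),
            class = "golgi_population")
}

#' @export
print.golgi_population <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<golgi_population: %d objects>\n", s$n_total))
  cat(sprintf("  ring %d | solid %d | rejected %d\n", s$n_ring, s$n_solid, s$n_rejected))
  cat(sprintf("  fraction solid (of classified): %.3f\n", s$fraction_solid))
  cat(sprintf("  diameter: mean %.1f, median %.1f, sd %.1f nm (%s widths)\n",
              s$mean_diameter_nm, s$median_diameter_nm, s$sd_diameter_nm,
              x$width_definition))
  invisible(x)
}

#' @rdname analyze_population
#' @param x A `golgi_population`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.golgi_population <- function(x, ...) x$objects

#' @rdname analyze_population
#' @exportS3Method generics::glance
glance.golgi_population <- function(x, ...) x$summary

#' Two-group comparison with F-test-guided t-test
#'
#' Implements the variance-screened two-sample comparison: a two-sided
#' F-test on the variance ratio decides whether to use the pooled-variance
#' Student's t-test (variances compatible) or Welch's unequal-variance
#' t-test, and the selected two-tailed t-test is then applied.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least two values
#'   and nonzero variance.
#' @param alpha_var Significance level for the F-test used to choose the
#'   t-test flavour (default 0.05).
#'
#' @return A one-row tibble of class `group_comparison`: `statistic`
#'   (t, computed as a - b), `df`, `p_value` (two-tailed),
#'   `variance_test_p`, `method` (`"student_pooled"` or `"welch"`),
#'   `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @examples
#' compare_groups(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
#' @export
compare_groups <- function(sample_a, sample_b, alpha_var = 0.05) {
  check_sample <- function(s, name) {
    if (!is.numeric(s) || sum(is.finite(s)) < 2L) {
      abort(sprintf("`%s` must contain at least two finite values.", name))
    }
    s <- s[is.finite(s)]
    if (var(s) == 0) abort(sprintf("`%s` has zero variance.", name))
    s
  }
  sample_a <- check_sample(sample_a, "sample_a")
  sample_b <- check_sample(sample_b, "sample_b")
  check_number(alpha_var, "alpha_var", min = 0, max = 1, strict_min = TRUE)

  p_var <- stats::var.test(sample_a, sample_b)$p.value
  welch <- p_var < alpha_var
  tt <- stats::t.test(sample_a, sample_b, var.equal = !welch,
                      alternative = "two.sided")
  out <- tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, variance_test_p = p_var,
    method = if (welch) "welch" else "student_pooled",
    mean_a = mean(sample_a), mean_b = mean(sample_b),
    n_a = length(sample_a), n_b = length(sample_b)
  )
  class(out) <- c("group_comparison", class(out))
  out
}
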