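# Shared fixtures and independent oracles used across test files.

# Imaging with all noise sources off (and optionally no background).
quiet_imaging <- function(background = 10, ...) {
  imaging_params(background = background, photon_scale = 0, read_noise_sd = 0, ...)
}

# Clean single/double Gaussian profile on the standard transect grid.
make_profile <- function(b = 10, A1 = 100, mu1 = 0, s1 = 113,
                         A2 = 0, mu2 = 0, s2 = 113,
                         step = 66.5, half = 1330, id = "p1") {
  x <- seq(-half, half, by = step)
  y <- b + A1 * exp(-(x - mu1)^2 / (2 * s1^2)) +
    A2 * exp(-(x - mu2)^2 / (2 * s2^2))
  tibble::tibble(source_id = id, position_nm = x, intensity = y)
}

# Independent pooled/Welch t-test oracle from the textbook formulas.
t_test_oracle <- function(a, b, pooled) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Two-sided F-test p-value oracle.
f_test_oracle <- function(a, b) {
  f <- var(a) / var(b)
  df1 <- length(a) - 1; df2 <- length(b) - 1
  p <- pf(f, df1, df2)
  2 * min(p, 1 - p)
}

# Direct pixel-sum Manders oracle on raw arrays.
manders_oracle <- function(a, b, ta, tb) {
  list(M1 = sum(a[a > ta & b > tb]) / sum(a[a > ta]),
       M2 = sum(b[a > ta & b > tb]) / sum(b[b > tb]))
}

# Type-7 quantile by explicit linear interpolation.
quantile7_oracle <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
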