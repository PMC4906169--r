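#' Manders co-localization coefficients
#'
#' Thresholded Manders coefficients for a registered two-channel image
#' pair. `M1` is the fraction of channel-A intensity (summed over pixels
#' where A exceeds its threshold) that falls on pixels where B also exceeds
#' its threshold; `M2` is the symmetric quantity for channel B. Thresholds
#' default to per-channel Otsu; pass both thresholds for manual parity with
#' interactively chosen values.
#'
#' @param channel_a,channel_b Numeric matrices of identical shape.
#' @param threshold_a,threshold_b Manual thresholds; both `NULL` (default)
#'   selects per-channel Otsu.
#'
#' @return One-row tibble of class `coloc_result`: `M1`, `M2`,
#'   `threshold_a`, `threshold_b`, `method` (`"otsu"` or `"manual"`). A
#'   channel with no above-threshold signal yields `NA` for its coefficient
#'   with a warning.
#' @examples
#' a <- matrix(0, 10, 10); a[2:4, 2:4] <- 100
#' manders(a, a, threshold_a = 50, threshold_b = 50) # M1 = M2 = 1
#' @export
manders <- function(channel_a, channel_b, threshold_a = NULL, threshold_b = NULL) {
  stopifnot(is.matrix(channel_a), is.matrix(channel_b))
  if (!all(dim(channel_a) == dim(channel_b))) {
    abort("`channel_a` and `channel_b` must have identical dimensions.")
  }
  manual <- !is.null(threshold_a) || !is.null(threshold_b)
  if (manual && (is.null(threshold_a) || is.null(threshold_b))) {
    abort("Provide both thresholds or neither.")
  }
  if (!manual) {
    threshold_a <- otsu_threshold(channel_a)
    threshold_b <- otsu_threshold(channel_b)
  }
  above_a <- channel_a > threshold_a
  above_b <- channel_b > threshold_b

  coef_for <- function(src, src_above, other_above, name) {
    denom <- sum(src[src_above])
    if (!any(src_above) || denom <= 0) {
      warn(sprintf("No above-threshold signal in channel %s; %s is undefined.",
                   name, if (name == "A") "M1" else "M2"))
      return(NA_real_)
    }
    sum(src[src_above & other_above]) / denom
  }
  out <- tibble(
    M1 = coef_for(channel_a, above_a, above_b, "A"),
    M2 = coef_for(channel_b, above_b, above_a, "B"),
    threshold_a = threshold_a, threshold_b = threshold_b,
    method = if (manual) "manual" else "otsu"
  )
  class(out) <- c("coloc_result", class(out))
  out
}

# Otsu threshold on an arbitrary-range image (EBImage's otsu works on [0,1]).
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng)), range = c(0, 1)) *
    diff(rng) + rng[1]
}
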