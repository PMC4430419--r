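#' Yen automatic threshold
#'
#' Computes the threshold maximizing Yen's maximum-correlation criterion on a
#' 256-bin intensity histogram. For a split after bin `t`, with foreground /
#' background cumulative probabilities `P1` and `1 - P1` and cumulative
#' squared bin probabilities `S1` and `S2`, the criterion is
#' `ln(P1^2 (1-P1)^2 / (S1 S2))`; the returned threshold is the center of the
#' lowest bin attaining the maximum, so ties break toward the lowest
#' threshold.
#'
#' @param x Numeric vector or matrix of intensities with at least two
#'   distinct values.
#' @param n_bins Number of histogram bins (default 256, used for all bit
#'   depths; binning spans the observed intensity range).
#' @return Scalar threshold on the intensity scale of `x`.
#' @seealso [binarize_yen()]
#' @export
yen_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  rng <- range(v)
  if (diff(rng) == 0) stop("degenerate histogram: image has a single gray value")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins)
  p <- tabulate(idx, nbins = n_bins) / length(v)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  P1 <- cumsum(p)
  S1 <- cumsum(p^2)
  S2 <- sum(p^2) - S1
  # candidate splits after bins 1..n_bins-1
  t <- seq_len(n_bins - 1)
  crit <- ifelse(P1[t] > 0 & P1[t] < 1 & S1[t] > 0 & S2[t] > 0,
                 2 * log(P1[t] * (1 - P1[t])) - log(S1[t] * S2[t]),
                 -Inf)
  if (all(!is.finite(crit))) stop("degenerate histogram: Yen criterion undefined")
  centers[which.max(crit)]
}

#' Binarize an image by Yen autothresholding
#'
#' @param img 2-D numeric matrix with at least two distinct gray values.
#' @param n_bins Histogram bins passed to [yen_threshold()].
#' @return List with `threshold` (gray value) and `mask`
#'   (logical matrix, `img > threshold`).
#' @export
binarize_yen <- function(img, n_bins = 256) {
  thr <- yen_threshold(img, n_bins = n_bins)
  mask <- img > thr
  list(threshold = thr, mask = mask)
}
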