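#' Oxygen consumption rate from an O2 trace
#'
#' Fits the straight portion of a dissolved-oxygen time trace and reports
#' the consumption rate normalized to protein content. The straight portion
#' is found by scanning all contiguous windows covering at least
#' `min_frac` of the trace and keeping the one with the best linear fit
#' (highest R^2, ties broken toward the longer window, so an exactly linear
#' trace selects the full trace). If even the best window has
#' `R^2 < r2_threshold`, the whole trace is used with a warning; this rule
#' excludes an initial nonlinear equilibration segment, whose inclusion
#' would bias the slope while still fitting deceptively well overall. The
#' rate is the negated fitted slope divided by `protein_mg`.
#'
#' @param time_min Time points in minutes (>= 10 points, increasing).
#' @param o2 Oxygen concentration at each time point.
#' @param protein_mg Protein content in milligrams (> 0).
#' @param r2_threshold Minimum R^2 for a window to count as straight
#'   (default 0.99).
#' @param min_frac Minimum window length as a fraction of the trace
#'   (default 0.5).
#' @return List with `rate` (concentration units per minute per mg
#'   protein), `slope`, `r_squared`, `window` (index range used),
#'   `used_full_trace`, `increasing_flag` (`TRUE` if O2 rises over the
#'   fitted window).
#' @export
respiration_rate <- function(time_min, o2, protein_mg,
                             r2_threshold = 0.99, min_frac = 0.5) {
  n <- length(time_min)
  if (length(o2) != n) stop("`time_min` and `o2` differ in length")
  if (n < 10L) stop("need at least 10 points")
  if (protein_mg <= 0) stop("`protein_mg` must be > 0")
  min_len <- max(2L, ceiling(min_frac * n))
  # O(1) per-window OLS via prefix sums
  cx <- cumsum(time_min); cy <- cumsum(o2)
  cxx <- cumsum(time_min^2); cyy <- cumsum(o2^2); cxy <- cumsum(time_min * o2)
  seg <- function(cs, i, j) cs[j] - if (i > 1L) cs[i - 1L] else 0
  best <- NULL
  for (i in seq_len(n - min_len + 1L)) {
    js <- (i + min_len - 1L):n
    m <- js - i + 1L
    sx <- seg(cx, i, js); sy <- seg(cy, i, js)
    sxx <- seg(cxx, i, js); syy <- seg(cyy, i, js); sxy <- seg(cxy, i, js)
    ssxx <- sxx - sx^2 / m
    ssyy <- syy - sy^2 / m
    ssxy <- sxy - sx * sy / m
    r2 <- ifelse(ssxx > 0 & ssyy > 0, ssxy^2 / (ssxx * ssyy), 0)
    # best fit first, longer window on (near-exact) ties
    k <- which.max(r2 + m * 1e-12)
    cand <- list(i = i, j = js[k], len = m[k], r2 = r2[k],
                 slope = ssxy[k] / ssxx[k])
    if (is.null(best) || cand$r2 > best$r2 + 1e-12 ||
        (abs(cand$r2 - best$r2) <= 1e-12 && cand$len > best$len)) {
      best <- cand
    }
  }
  used_full <- FALSE
  if (best$r2 < r2_threshold) {
    warning("no window reached R^2 >= ", r2_threshold, "; using full trace")
    used_full <- TRUE
    sxx <- seg(cxx, 1L, n) - seg(cx, 1L, n)^2 / n
    sxy <- seg(cxy, 1L, n) - seg(cx, 1L, n) * seg(cy, 1L, n) / n
    syy <- seg(cyy, 1L, n) - seg(cy, 1L, n)^2 / n
    best <- list(i = 1L, j = n, len = n,
                 r2 = if (sxx > 0 && syy > 0) sxy^2 / (sxx * syy) else 0,
                 slope = sxy / sxx)
  }
  increasing <- best$slope > 0
  if (increasing) warning("O2 increases over the fitted window")
  list(rate = -best$slope / protein_mg,
       slope = best$slope,
       r_squared = best$r2,
       window = c(best$i, best$j),
       used_full_trace = used_full,
       increasing_flag = increasing)
}
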