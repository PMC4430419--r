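#' Quinone redox ratio
#'
#' Percentage of the coenzyme Q9 pool in the reduced (ubiquinol) form,
#' `100 * reduced / (reduced + oxidized)`, from pre-integrated HPLC peak
#' areas. Scale-invariant in the two areas; vectorized.
#'
#' @param area_reduced Peak area of the reduced form (UQ9-H2), >= 0.
#' @param area_oxidized Peak area of the oxidized form (UQ9), >= 0.
#' @return Percent reduced, in `[0, 100]`.
#' @export
redox_ratio <- function(area_reduced, area_oxidized) {
  if (any(area_reduced < 0) || any(area_oxidized < 0)) {
    stop("peak areas must be non-negative")
  }
  total <- area_reduced + area_oxidized
  if (any(total == 0)) stop("both peak areas are zero")
  100 * area_reduced / total
}
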