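#' Gray-level co-occurrence matrix
#'
#' Counts pairs of quantized intensities at a fixed pixel offset and
#' normalizes them to probabilities. Quantization is linear binning of the
#' full bit-depth range `[0, max_gray]` into `n_levels` levels, so images of
#' the same bit depth are binned identically regardless of content.
#'
#' @param img 2-D numeric matrix in native gray units.
#' @param offset Integer `(dr, dc)` displacement; `c(0, 1)` is the
#'   one-pixel horizontal offset, `c(1, 0)` vertical.
#' @param n_levels Number of gray levels (default 256 for 8-bit input;
#'   64 is recommended for 16-bit input).
#' @param max_gray Full-scale gray value (from `img`'s attribute, else 255).
#' @param symmetric If `TRUE`, pairs are counted in both directions so the
#'   matrix is symmetric (default `FALSE`).
#' @return Object of class `texture_matrix`: list with `P` (`n_levels` x
#'   `n_levels` probability matrix, rows = level of the first pixel),
#'   `n_levels`, `offset`, `symmetric`.
#' @export
glcm_compute <- function(img, offset = c(0, 1), n_levels = 256,
                         max_gray = NULL, symmetric = FALSE) {
  mg <- .max_gray_of(img, max_gray)
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  n <- nrow(img); m <- ncol(img)
  if (abs(dr) >= n || abs(dc) >= m) stop("offset larger than image")
  q <- pmin(floor(img / (mg + 1) * n_levels), n_levels - 1)  # levels 0..N-1
  rs <- seq_len(n - abs(dr)); cs <- seq_len(m - abs(dc))
  a <- q[rs + max(0L, -dr), cs + max(0L, -dc)]
  b <- q[rs + max(0L, dr), cs + max(0L, dc)]
  tab <- tabulate(a * n_levels + b + 1, nbins = n_levels^2)
  counts <- matrix(tab, n_levels, n_levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(
    list(P = counts / sum(counts), n_levels = n_levels,
         offset = c(dr, dc), symmetric = symmetric),
    class = "texture_matrix")
}

#' Haralick texture features of a co-occurrence matrix
#'
#' Evaluates, with natural logarithms and the convention `0 * ln 0 = 0`:
#' entropy `sum_ij P_ij (-ln P_ij)` (nats), contrast
#' `sum_ij P_ij (i - j)^2` (squared gray-level units) and correlation
#' `sum_ij P_ij (i - mu_i)(j - mu_j) / sqrt(sigma_i^2 sigma_j^2)`, where
#' `mu` and `sigma^2` are the marginal means and variances of `P`.
#' Correlation is undefined (`NaN`) when either marginal variance is zero,
#' e.g. for a constant image.
#'
#' @param tm A [glcm_compute()] result, or a bare probability matrix.
#' @return List with `entropy`, `contrast`, `correlation`.
#' @export
glcm_features <- function(tm) {
  P <- if (inherits(tm, "texture_matrix")) tm$P else tm
  if (abs(sum(P) - 1) > 1e-8) stop("co-occurrence matrix must sum to 1")
  N <- nrow(P)
  lev <- 0:(N - 1)
  nz <- P > 0
  entropy <- -sum(P[nz] * log(P[nz]))
  D <- outer(lev, lev, function(i, j) (i - j)^2)
  contrast <- sum(P * D)
  pi_ <- rowSums(P); pj <- colSums(P)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj)
  var_i <- sum((lev - mu_i)^2 * pi_); var_j <- sum((lev - mu_j)^2 * pj)
  correlation <- if (var_i <= 0 || var_j <= 0) {
    NaN
  } else {
    sum(P * outer(lev - mu_i, lev - mu_j)) / sqrt(var_i * var_j)
  }
  list(entropy = entropy, contrast = contrast, correlation = correlation)
}

#' Directionally averaged texture features of an image
#'
#' Computes the three texture features from a horizontal (`(0,1)`) and a
#' vertical (`(1,0)`) one-pixel-offset co-occurrence matrix and returns
#' their arithmetic means, the per-image texture summary used in the
#' feature record.
#'
#' @inheritParams glcm_compute
#' @return List with `Entropy`, `Contrast`, `Correlation`.
#' @export
texture_summary <- function(img, n_levels = 256, max_gray = NULL,
                            symmetric = FALSE) {
  fh <- glcm_features(glcm_compute(img, c(0, 1), n_levels, max_gray, symmetric))
  fv <- glcm_features(glcm_compute(img, c(1, 0), n_levels, max_gray, symmetric))
  list(Entropy = (fh$entropy + fv$entropy) / 2,
       Contrast = (fh$contrast + fv$contrast) / 2,
       Correlation = (fh$correlation + fv$correlation) / 2)
}
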