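# Structuring-element offsets and heights for a ball of the given radius:
# all (dr, dc) with dr^2 + dc^2 <= r^2, with hemisphere height
# h = sqrt(r^2 - d^2) in gray units.
.ball_element <- function(radius) {
  r <- as.integer(ceiling(radius))
  d <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- d$dr^2 + d$dc^2 <= radius^2
  d <- d[keep, , drop = FALSE]
  list(dr = d$dr, dc = d$dc,
       h = sqrt(pmax(0, radius^2 - (d$dr^2 + d$dc^2))))
}

# Non-flat grayscale erosion/dilation by the ball element; out-of-bounds
# pixels are ignored (pad with +/-Inf).
.gray_morph <- function(img, elem, op = c("erode", "dilate")) {
  op <- match.arg(op)
  n <- nrow(img); m <- ncol(img)
  r <- max(abs(c(elem$dr, elem$dc)))
  pad_val <- if (op == "erode") Inf else -Inf
  padded <- matrix(pad_val, n + 2 * r, m + 2 * r)
  padded[(r + 1):(r + n), (r + 1):(r + m)] <- img
  acc <- matrix(if (op == "erode") Inf else -Inf, n, m)
  for (k in seq_along(elem$dr)) {
    dr <- elem$dr[k]; dc <- elem$dc[k]; h <- elem$h[k]
    sub <- padded[(r + 1 + dr):(r + n + dr), (r + 1 + dc):(r + m + dc)]
    if (op == "erode") {
      acc <- pmin(acc, sub - h)
    } else {
      acc <- pmax(acc, sub + h)
    }
  }
  acc
}

#' Rolling-ball background subtraction
#'
#' Estimates a smoothly varying background as the grayscale opening of the
#' image by a ball-shaped (hemispherical) structuring element of the given
#' radius, and subtracts it, clipping at zero. Structures narrower than the
#' ball are removed from the background estimate and therefore preserved in
#' the output; a constant image maps to all zeros, and adding a constant
#' offset to the input does not change the output.
#'
#' @param img 2-D numeric matrix (a projected image).
#' @param ball_radius_px Ball radius in pixels (default 15). Must be >= 1.
#' @return Matrix of the same shape; attributes of `img` are preserved and
#'   the background estimate is attached as attribute `background`.
#' @export
subtract_background <- function(img, ball_radius_px = 15) {
  if (ball_radius_px < 1) stop("`ball_radius_px` must be >= 1")
  if (2 * ball_radius_px + 1 > min(dim(img))) {
    warning("ball radius exceeds image extent; using global minimum as background")
    bg <- matrix(min(img), nrow(img), ncol(img))
  } else {
    elem <- .ball_element(ball_radius_px)
    bg <- .gray_morph(.gray_morph(img, elem, "erode"), elem, "dilate")
    bg <- pmin(bg, img)  # opening is anti-extensive up to discretization
  }
  out <- pmax(img - bg, 0)
  attributes(out) <- attributes(img)
  attr(out, "background") <- bg
  out
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Enhances local contrast by equalizing intensity histograms over tiles of
#' roughly `block_size_px` pixels, limiting the slope of the transfer
#' function to `clip_limit` to avoid amplifying noise in flat regions. Tiles
#' are bilinearly interpolated, so the mapping is rank-preserving within each
#' tile. If the block size is at least the smaller image dimension, global
#' histogram equalization is applied instead, with a warning.
#'
#' @param img 2-D numeric matrix in native gray units.
#' @param block_size_px Approximate tile edge length in pixels (default 15).
#' @param clip_limit Contrast-limiting slope (default 3).
#' @param max_gray Full-scale gray value; taken from `img`'s `max_gray`
#'   attribute when present, else 255.
#' @return Matrix of the same shape in `[0, max_gray]`.
#' @export
enhance_local_contrast <- function(img, block_size_px = 15, clip_limit = 3,
                                   max_gray = NULL) {
  if (block_size_px < 2) stop("`block_size_px` must be >= 2")
  mg <- .max_gray_of(img, max_gray)
  if (diff(range(img)) == 0) {
    return(img)  # nothing to equalize
  }
  x01 <- pmin(pmax(img / mg, 0), 1)
  if (block_size_px >= min(dim(img))) {
    warning("block size exceeds image extent; falling back to global equalization")
    out <- EBImage::equalize(x01, range = c(0, 1), levels = 256) * mg
  } else {
    nt_r <- max(2L, round(nrow(img) / block_size_px))
    nt_c <- max(2L, round(ncol(img) / block_size_px))
    # EBImage::clahe needs dimensions that are multiples of the tile counts:
    # pad by edge replication, run, crop.
    pr <- ceiling(nrow(img) / nt_r) * nt_r
    pc <- ceiling(ncol(img) / nt_c) * nt_c
    pad <- x01[c(seq_len(nrow(img)), rep(nrow(img), pr - nrow(img))),
               c(seq_len(ncol(img)), rep(ncol(img), pc - ncol(img))),
               drop = FALSE]
    eq <- EBImage::clahe(pad, nx = nt_r, ny = nt_c, limit = clip_limit)
    out <- as.matrix(eq)[seq_len(nrow(img)), seq_len(ncol(img))] * mg
  }
  out <- pmin(pmax(out, 0), mg)
  attributes(out) <- attributes(img)
  out
}

# Zero-sum Laplacian-of-Gaussian kernel at scale sigma.
.log_kernel <- function(sigma) {
  half <- max(2L, as.integer(ceiling(3 * sigma)))
  ax <- -half:half
  g <- expand.grid(x = ax, y = ax)
  r2 <- g$x^2 + g$y^2
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  k <- k - mean(k)  # exact zero response on constant images
  matrix(k, length(ax), length(ax))
}

#' Multi-scale Laplacian enhancement of bright structures
#'
#' Convolves the image with scale-normalized Laplacian-of-Gaussian kernels at
#' each scale and takes the pixel-wise maximum of the negated responses, so
#' bright blobs and tubules of any width in the scale range produce a strong
#' positive response at their centerline. Negative responses are clipped to 0.
#'
#' @param img 2-D numeric matrix.
#' @param scales_px Positive Gaussian scales (sigma, pixels); default
#'   `c(1, 2)`, matched to mitochondrial tubule and fragment radii of
#'   roughly 1.4-2.8 px (0.3-0.6 um) at 0.2 um/px. Larger scales respond in
#'   a wide halo around thin structures, which inflates masks and can
#'   bridge neighboring objects.
#' @return Non-negative response matrix of the same shape.
#' @export
multiscale_laplacian <- function(img, scales_px = c(1, 2)) {
  if (length(scales_px) == 0) stop("`scales_px` must contain at least one scale")
  if (any(scales_px <= 0)) stop("scales must be positive")
  resp <- matrix(0, nrow(img), ncol(img))
  x <- matrix(as.numeric(img), nrow(img), ncol(img))
  for (s in scales_px) {
    k <- .log_kernel(s)
    r <- -s^2 * EBImage::filter2(x, k, boundary = "replicate")
    resp <- pmax(resp, r)
  }
  resp <- pmax(resp, 0)
  # suppress FFT round-off so a constant image maps to an exact zero response
  resp[resp < 1e-10 * max(abs(x), 1)] <- 0
  attributes(resp) <- attributes(img)
  resp
}
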