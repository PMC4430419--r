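#' Fluorescence image stack
#'
#' Container for a single-channel multi-slice microscopy stack. Voxels are
#' stored as a 3-D numeric array indexed `[slice, row, col]` in native gray
#' values (0..`max_gray`), with the lateral pixel size in micrometers.
#'
#' @param voxels 3-D numeric array (slices x rows x cols) of non-negative
#'   intensities. A plain matrix is promoted to a single-slice stack.
#' @param pixel_size_um Lateral pixel size in micrometers per pixel
#'   (default 0.2, the confocal acquisition setting the pipeline assumes).
#' @param bit_depth Integer, 8 or 16; determines `max_gray = 2^bit_depth - 1`.
#' @param metadata Optional named list of free-form metadata.
#'
#' @return An object of class `image_stack` with fields `voxels`,
#'   `pixel_size_um`, `bit_depth`, `max_gray` and `metadata`.
#' @export
image_stack <- function(voxels, pixel_size_um = 0.2, bit_depth = 8,
                        metadata = list()) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, c(1L, nrow(voxels), ncol(voxels)))
  }
  if (length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3-D array (slices x rows x cols)")
  }
  if (any(dim(voxels) <= 0L)) stop("non-positive image dimensions")
  if (dim(voxels)[1] < 1L) stop("stack must contain at least one slice")
  if (any(voxels < 0)) stop("intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be > 0")
  }
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  structure(
    list(voxels = voxels,
         pixel_size_um = pixel_size_um,
         bit_depth = as.integer(bit_depth),
         max_gray = 2^as.integer(bit_depth) - 1,
         metadata = metadata),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d slice(s), %d x %d px, %d-bit, %.3g um/px\n",
              d[1], d[2], d[3], x$bit_depth, x$pixel_size_um))
  invisible(x)
}

#' Number of slices in a stack
#' @param stack An [image_stack()].
#' @return Integer slice count.
#' @export
n_slices <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  dim(stack$voxels)[1]
}

#' Read a multi-page TIFF into an image stack
#'
#' @param path Path to a single-channel 8- or 16-bit multi-page TIFF.
#' @param pixel_size_um Pixel size in micrometers (TIFF tags are not parsed).
#' @param bit_depth Bit depth used to rescale the `[0,1]` values returned by
#'   the TIFF reader back to native gray levels.
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path, pixel_size_um = 0.2, bit_depth = 8) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse an accidental channel dim
    p
  })
  max_gray <- 2^bit_depth - 1
  vox <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) vox[i, , ] <- round(pages[[i]] * max_gray)
  image_stack(vox, pixel_size_um = pixel_size_um, bit_depth = bit_depth,
              metadata = list(source = path))
}

#' Write an image stack as a multi-page TIFF
#'
#' Intensities are scaled by `max_gray` into the `[0,1]` range the TIFF writer
#' expects and stored at the stack's bit depth.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(n_slices(stack)), function(i) {
    pmin(pmax(stack$voxels[i, , ] / stack$max_gray, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  invisible(path)
}

#' Quality-triage stack slices by intensity variance
#'
#' Removes uninformative (defocused or reflective) slices before projection.
#' The per-slice quality statistic is the population variance of the slice's
#' pixel intensities in squared native gray units; only slices whose statistic
#' exceeds `qc_threshold` are retained, in their original order. A perfectly
#' uniform slice scores 0 and is always dropped.
#'
#' @param stack An [image_stack()].
#' @param qc_threshold Retention threshold on the per-slice statistic
#'   (default 1, i.e. "variance > 1").
#' @return An [image_stack()] of the retained slices. The per-slice statistic,
#'   the retained indices and the threshold are recorded in
#'   `metadata$qc` (fields `statistic`, `retained`, `threshold`).
#' @export
triage_slices <- function(stack, qc_threshold = 1.0) {
  stopifnot(inherits(stack, "image_stack"))
  ns <- n_slices(stack)
  stat <- vapply(seq_len(ns), function(i) {
    x <- stack$voxels[i, , ]
    mean((x - mean(x))^2)
  }, numeric(1))
  keep <- which(stat > qc_threshold)
  if (length(keep) == 0L) {
    stop("empty after triage: no slice has QC statistic > ", qc_threshold)
  }
  md <- stack$metadata
  md$qc <- list(statistic = stat, retained = keep, threshold = qc_threshold)
  image_stack(stack$voxels[keep, , , drop = FALSE],
              pixel_size_um = stack$pixel_size_um,
              bit_depth = stack$bit_depth, metadata = md)
}

#' Maximum-intensity projection
#'
#' Collapses a stack to a 2-D image whose pixel `(r, c)` is the maximum of
#' that pixel over all slices.
#'
#' @param stack An [image_stack()] (typically after [triage_slices()]).
#' @return Numeric matrix (rows x cols) with attributes `pixel_size_um`,
#'   `max_gray` and `provenance` (the projected slice indices within `stack`).
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  proj <- apply(stack$voxels, c(2, 3), max)
  attr(proj, "pixel_size_um") <- stack$pixel_size_um
  attr(proj, "max_gray") <- stack$max_gray
  attr(proj, "provenance") <- seq_len(n_slices(stack))
  proj
}

# Max gray value for a projected image / plain matrix, with 8-bit fallback.
.max_gray_of <- function(img, max_gray = NULL) {
  if (!is.null(max_gray)) return(max_gray)
  mg <- attr(img, "max_gray")
  if (is.null(mg)) 255 else mg
}
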