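# Connected-component labeling of a logical mask at 4- or 8-connectivity.
# Components are numbered 1..n in order of first appearance in a column-major
# raster scan, so labeling is deterministic.
.label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  n <- nrow(mask); m <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, n, m)
  if (length(fg) == 0L) return(lab)
  id <- integer(n * m)
  id[fg] <- seq_along(fg)
  rr <- ((fg - 1L) %% n) + 1L
  cc <- ((fg - 1L) %/% n) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (o in offs) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= n & c2 >= 1L & c2 <= m
    nb <- (c2[ok] - 1L) * n + r2[ok]
    hit <- id[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(id[fg[ok]][hit], id[nb][hit]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel by first appearance in raster order (fg is already column-major)
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  lab[fg] <- relab[memb]
  lab
}

#' Extract size-filtered labeled objects from a binary mask
#'
#' Labels connected components of the mask and keeps only objects strictly
#' larger than `min_size_px` pixels (the "> 12 pixels" particle filter), then
#' renumbers the survivors 1..n in raster order.
#'
#' @param mask Logical matrix, or numeric matrix containing only 0/1.
#' @param min_size_px Minimum size threshold; components with
#'   `size <= min_size_px` are removed (strict inequality, default 12).
#' @param connectivity Pixel connectivity, 4 or 8 (default 8, the ImageJ
#'   particle-analysis convention).
#' @return An object of class `labeled_objects`: list with `label_image`
#'   (integer matrix, 0 = background), `n_objects`, `sizes` (pixel counts),
#'   `min_size_px` and `connectivity`.
#' @export
extract_objects <- function(mask, min_size_px = 12, connectivity = 8) {
  if (is.logical(mask)) {
    lmask <- mask
  } else if (is.numeric(mask) && all(mask %in% c(0, 1))) {
    lmask <- mask == 1
  } else {
    stop("`mask` must be binary (logical or 0/1)")
  }
  lab <- .label_components(lmask, connectivity = connectivity)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes > min_size_px)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
    sizes <- sizes[keep]
  } else {
    sizes <- integer(0)
  }
  structure(
    list(label_image = lab,
         n_objects = length(sizes),
         sizes = as.integer(sizes),
         min_size_px = min_size_px,
         connectivity = connectivity),
    class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %d object(s) > %g px (%d-connectivity)\n",
              x$n_objects, x$min_size_px, x$connectivity))
  invisible(x)
}

#' Segmentation pipeline configuration
#'
#' Bundles the tunable parameters of [run_pipeline()] with their defaults:
#' slice triage at variance > 1, rolling-ball radius 15, local-contrast block
#' size 15 (clip limit 3), Laplacian scales {1, 2} px, Yen thresholding of
#' the Laplacian response, and particles > 12 px at 8-connectivity.
#'
#' @param qc_threshold Slice-triage variance threshold.
#' @param ball_radius_px Rolling-ball background radius (pixels).
#' @param block_size_px CLAHE block size (pixels).
#' @param clip_limit CLAHE contrast limit.
#' @param scales_px Laplacian-of-Gaussian scales (pixels).
#' @param threshold_input Image handed to the Yen threshold: the multi-scale
#'   `"laplacian"` response (default; the enhancement step precedes
#'   binarization) or the `"contrast"`-enhanced image.
#' @param min_size_px Particle size filter (strict; objects must exceed it).
#' @param connectivity 4 or 8.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc_threshold = 1.0, ball_radius_px = 15,
                            block_size_px = 15, clip_limit = 3,
                            scales_px = c(1, 2),
                            threshold_input = c("laplacian", "contrast"),
                            min_size_px = 12, connectivity = 8) {
  structure(
    list(qc_threshold = qc_threshold, ball_radius_px = ball_radius_px,
         block_size_px = block_size_px, clip_limit = clip_limit,
         scales_px = scales_px,
         threshold_input = match.arg(threshold_input),
         min_size_px = min_size_px, connectivity = connectivity),
    class = "pipeline_config")
}

#' Run the full segmentation pipeline on a stack
#'
#' Composes slice triage, maximum-intensity projection, rolling-ball
#' background subtraction, local contrast enhancement, multi-scale Laplacian
#' enhancement, Yen binarization and size-filtered object extraction. The
#' unprocessed maximum projection of the triaged stack is returned alongside
#' the objects because per-object intensity and whole-image texture metrics
#' are measured on the original (unenhanced) image.
#'
#' @param stack An [image_stack()].
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with `objects`
#'   ([extract_objects()] output), `preprocessed` (the image that was
#'   thresholded), `original_projection`, `mask`, `threshold`, and `log`
#'   (per-stage parameters, per-slice QC statistics, retained slices).
#' @export
run_pipeline <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "image_stack"))
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  triaged <- triage_slices(stack, qc_threshold = config$qc_threshold)
  original <- max_project(triaged)
  bgsub <- subtract_background(original, ball_radius_px = config$ball_radius_px)
  enhanced <- enhance_local_contrast(bgsub, block_size_px = config$block_size_px,
                                     clip_limit = config$clip_limit,
                                     max_gray = stack$max_gray)
  lapl <- multiscale_laplacian(enhanced, scales_px = config$scales_px)
  to_thresh <- switch(config$threshold_input,
                      laplacian = lapl,
                      contrast = enhanced)
  bin <- binarize_yen(to_thresh)
  objects <- extract_objects(bin$mask, min_size_px = config$min_size_px,
                             connectivity = config$connectivity)
  structure(
    list(objects = objects,
         preprocessed = to_thresh,
         original_projection = original,
         mask = bin$mask,
         threshold = bin$threshold,
         log = list(config = unclass(config),
                    qc = triaged$metadata$qc,
                    n_slices_in = n_slices(stack),
                    n_slices_retained = n_slices(triaged),
                    yen_threshold = bin$threshold,
                    n_objects = objects$n_objects)),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d/%d slices retained, Yen threshold %.4g, %d object(s)\n",
    x$log$n_slices_retained, x$log$n_slices_in, x$threshold,
    x$objects$n_objects))
  invisible(x)
}
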