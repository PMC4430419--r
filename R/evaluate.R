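#' Match segmented objects against ground truth
#'
#' Greedy one-to-one matching of predicted and true labeled objects by
#' intersection-over-union: candidate pairs are ranked by IoU and accepted
#' in decreasing order if both objects are still unmatched and the IoU
#' reaches `iou_threshold`. Precision, recall and F1 follow from the
#' matched (true positive), unmatched predicted (false positive) and
#' unmatched true (false negative) counts.
#'
#' @param predicted Integer label matrix (or [extract_objects()] result).
#' @param truth Integer label matrix of ground-truth objects.
#' @param iou_threshold Minimum IoU for a valid match (default 0.3).
#' @return List with `f1`, `precision`, `recall`, `tp`, `fp`, `fn`, and
#'   `matches` (`data.frame`: predicted label, true label, iou).
#' @export
match_objects <- function(predicted, truth, iou_threshold = 0.3) {
  pred <- if (inherits(predicted, "labeled_objects")) predicted$label_image else predicted
  if (!all(dim(pred) == dim(truth))) stop("label images differ in shape")
  np <- max(pred); nt <- max(truth)
  if (np == 0L || nt == 0L) {
    tp <- 0L; fp <- np; fn <- nt
    matches <- data.frame(predicted = integer(0), truth = integer(0),
                          iou = numeric(0))
  } else {
    both <- pred > 0 & truth > 0
    inter <- table(factor(pred[both], levels = 1:np),
                   factor(truth[both], levels = 1:nt))
    sz_p <- tabulate(pred[pred > 0], nbins = np)
    sz_t <- tabulate(truth[truth > 0], nbins = nt)
    iou <- as.matrix(inter) /
      (outer(sz_p, sz_t, "+") - as.matrix(inter))
    cand <- which(iou >= iou_threshold, arr.ind = TRUE)
    ord <- order(iou[cand], decreasing = TRUE)
    used_p <- logical(np); used_t <- logical(nt)
    rows <- list()
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE; used_t[j] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(predicted = i, truth = j,
                                                iou = iou[i, j])
      }
    }
    matches <- if (length(rows)) do.call(rbind, rows) else
      data.frame(predicted = integer(0), truth = integer(0), iou = numeric(0))
    tp <- nrow(matches); fp <- np - tp; fn <- nt - tp
  }
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(f1 = f1, precision = precision, recall = recall,
       tp = tp, fp = fp, fn = fn, matches = matches)
}

#' Write a simulated stack, its ground truth and parameters to disk
#'
#' Stores the stack as a multi-page TIFF, the ground-truth labels as a
#' 16-bit TIFF and the phenotype parameters as a JSON sidecar (requires
#' the jsonlite package).
#'
#' @param sim A [simulate_network_stack()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Invisibly, the written paths.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stack_path <- file.path(dir, paste0(prefix, "_stack.tif"))
  labels_path <- file.path(dir, paste0(prefix, "_labels.tif"))
  json_path <- file.path(dir, paste0(prefix, "_params.json"))
  write_stack_tiff(sim$stack, stack_path)
  tiff::writeTIFF(sim$truth$labels / 65535, labels_path, bits.per.sample = 16)
  written <- c(stack_path, labels_path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- sim$stack$metadata
    jsonlite::write_json(
      list(phenotype = meta$phenotype, seed = meta$seed,
           n_objects = sim$truth$n_objects,
           in_focus_slices = sim$truth$in_focus_slices,
           defocused_slices = sim$truth$defocused_slices),
      json_path, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, json_path)
  }
  invisible(written)
}
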