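#' Summarize one image into a feature record
#'
#' Averages the per-object shape/intensity metrics (unweighted arithmetic
#' mean over objects by default) and appends the whole-image texture metrics
#' computed on the original (unenhanced, background-unsubtracted) projection,
#' yielding the one-row feature record that phenotype clustering consumes.
#' Images with zero objects produce a record with `NObjects = 0` and `NA`
#' shape fields, which the clustering front-end excludes.
#'
#' @param objects [extract_objects()] output for the image.
#' @param original The unenhanced maximum projection (numeric matrix);
#'   intensity and texture metrics are measured on it.
#' @param pixel_size_um Pixel size for areas in square micrometers.
#' @param image_id Identifier stored in the record.
#' @param condition Condition/treatment label stored in the record.
#' @param glcm_levels Gray levels for the texture matrices (default 256;
#'   use 64 for 16-bit input).
#' @param max_gray Full-scale gray value of `original` (attribute else 255).
#' @param area_weighted If `TRUE`, per-object shape metrics are averaged
#'   with area weights instead of the default unweighted mean.
#' @return One-row `data.frame`: `image_id`, `Condition`, the ten metric
#'   columns of [feature_metrics()], and `NObjects`.
#' @export
summarize_image <- function(objects, original, pixel_size_um = 0.2,
                            image_id = NA_character_,
                            condition = NA_character_,
                            glcm_levels = 256, max_gray = NULL,
                            area_weighted = FALSE) {
  per_obj <- object_metrics(objects, original, pixel_size_um)
  tex <- texture_summary(original, n_levels = glcm_levels, max_gray = max_gray)
  shape_cols <- c("Mean", "Area", "AR", "Feret", "Solidity", "Circ", "Round")
  if (nrow(per_obj) == 0L) {
    shp <- as.list(stats::setNames(rep(NA_real_, length(shape_cols)), shape_cols))
    n_obj <- 0L
  } else {
    w <- if (area_weighted) per_obj$Area else rep(1, nrow(per_obj))
    shp <- lapply(stats::setNames(shape_cols, shape_cols), function(cn) {
      sum(per_obj[[cn]] * w) / sum(w)
    })
    n_obj <- nrow(per_obj)
  }
  data.frame(image_id = image_id, Condition = condition,
             as.data.frame(shp), Entropy = tex$Entropy,
             Contrast = tex$Contrast, Correlation = tex$Correlation,
             NObjects = n_obj, stringsAsFactors = FALSE)
}

#' Write per-object and per-image feature tables as CSV
#'
#' @param per_object `data.frame` from [object_metrics()] (or `NULL`).
#' @param per_image `data.frame` of stacked [summarize_image()] records
#'   (or `NULL`).
#' @param object_path,image_path Output CSV paths (header row included).
#' @return Invisibly, the paths written.
#' @export
write_feature_csv <- function(per_object = NULL, per_image = NULL,
                              object_path = NULL, image_path = NULL) {
  written <- character(0)
  if (!is.null(per_object) && !is.null(object_path)) {
    utils::write.csv(per_object, object_path, row.names = FALSE)
    written <- c(written, object_path)
  }
  if (!is.null(per_image) && !is.null(image_path)) {
    utils::write.csv(per_image, image_path, row.names = FALSE)
    written <- c(written, image_path)
  }
  invisible(written)
}
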