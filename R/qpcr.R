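#' qPCR standard curve
#'
#' Linear calibration of threshold cycle against log10 template copies,
#' `Ct = slope * log10(copies) + intercept`. A valid amplification curve has
#' a negative slope (about -3.32 cycles per tenfold dilution at 100%
#' efficiency); the intercept is the Ct expected for a single copy.
#'
#' @param slope Cycles per log10(copies); must be negative for a usable
#'   curve (checked where it matters, e.g. [quantify_absolute()]).
#' @param intercept Ct at one copy.
#' @param r_squared Coefficient of determination of the fit (optional).
#' @return Object of class `standard_curve`.
#' @export
standard_curve <- function(slope, intercept, r_squared = NA_real_) {
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("`r_squared` must be in [0, 1]")
  }
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> Ct = %.4g * log10(copies) + %.4g (R^2 = %.4g)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Fit a standard curve from a dilution series
#'
#' Ordinary least squares of Ct on log10(copies), the calibration obtained
#' from tenfold plasmid dilutions of known concentration.
#'
#' @param copies Known template copy numbers (> 0), length >= 3.
#' @param ct Measured threshold cycles, same length.
#' @return A [standard_curve()] with slope, intercept and R squared.
#' @export
fit_standard_curve <- function(copies, ct) {
  if (length(copies) != length(ct)) stop("`copies` and `ct` differ in length")
  if (length(copies) < 3L) stop("need at least 3 calibration points")
  if (any(copies <= 0)) stop("copy numbers must be > 0")
  x <- log10(copies)
  if (diff(range(x)) == 0) stop("all dilutions identical; cannot fit a line")
  fit <- stats::lm(ct ~ x)
  sse <- sum(fit$residuals^2)
  sst <- sum((ct - mean(ct))^2)
  standard_curve(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (sst > 0) max(0, min(1, 1 - sse / sst)) else NA_real_)
}

#' Predict Ct from copies / invert Ct to copies
#'
#' @param curve A [standard_curve()].
#' @param copies Copy numbers (> 0).
#' @return Predicted Ct values.
#' @export
predict_ct <- function(curve, copies) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(copies <= 0)) stop("copy numbers must be > 0")
  curve$slope * log10(copies) + curve$intercept
}

#' @rdname predict_ct
#' @param ct Threshold cycles.
#' @return For `ct_to_copies`, template copies implied by each Ct.
#' @export
ct_to_copies <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0) stop("standard curve slope must be negative")
  10^((ct - curve$intercept) / curve$slope)
}

#' qPCR sample with replicate Ct values and scaling metadata
#'
#' Captures how a worm lysate reaches the PCR reaction: `worms_per_lysate`
#' animals lysed in `lysate_volume_ul` of buffer, diluted
#' `dilution_factor`-fold, with `template_volume_ul` of the dilution used as
#' template. The lysate volume is deliberately a required argument - the
#' copies-per-worm scale depends on it and no universal default exists.
#'
#' @param ct_values Numeric replicate threshold cycles (finite).
#' @param lysate_volume_ul Lysis volume in microliters (required).
#' @param dilution_factor Fold dilution before PCR (default 40).
#' @param template_volume_ul Template volume per reaction (default 2).
#' @param worms_per_lysate Animals per lysate (default 5).
#' @param id Optional sample identifier.
#' @return Object of class `qpcr_sample`.
#' @export
qpcr_sample <- function(ct_values, lysate_volume_ul, dilution_factor = 40,
                        template_volume_ul = 2, worms_per_lysate = 5,
                        id = NA_character_) {
  if (any(!is.finite(ct_values))) stop("Ct values must be finite")
  if (lysate_volume_ul <= 0 || template_volume_ul <= 0 || dilution_factor <= 0) {
    stop("volumes and dilution factor must be > 0")
  }
  if (worms_per_lysate < 1) stop("`worms_per_lysate` must be >= 1")
  structure(list(ct_values = as.numeric(ct_values),
                 lysate_volume_ul = lysate_volume_ul,
                 dilution_factor = dilution_factor,
                 template_volume_ul = template_volume_ul,
                 worms_per_lysate = worms_per_lysate,
                 id = id),
            class = "qpcr_sample")
}

#' Absolute quantification: copies per reaction and per worm
#'
#' Converts the sample's mean Ct through the standard curve to template
#' copies in the reaction, then scales by the dilution factor and the
#' lysate/template volume ratio and divides by the number of worms:
#' `copies_per_worm = copies_reaction * dilution_factor *
#' (lysate_volume / template_volume) / worms_per_lysate`.
#'
#' @param sample A [qpcr_sample()].
#' @param curve A [standard_curve()] with negative slope.
#' @return List with `copies_reaction`, `copies_per_worm`, `mean_ct`.
#' @export
quantify_absolute <- function(sample, curve) {
  stopifnot(inherits(sample, "qpcr_sample"))
  mean_ct <- mean(sample$ct_values)
  copies_reaction <- ct_to_copies(curve, mean_ct)
  copies_per_worm <- copies_reaction * sample$dilution_factor *
    (sample$lysate_volume_ul / sample$template_volume_ul) /
    sample$worms_per_lysate
  list(copies_reaction = copies_reaction,
       copies_per_worm = copies_per_worm,
       mean_ct = mean_ct)
}

#' Relative quantification against a reference with confidence intervals
#'
#' Expresses each sample's absolute copy number as a percentage of an
#' unexposed reference. The confidence interval is propagated from the
#' replicate Ct dispersion: a pooled-SD t-interval on the Ct difference
#' (`df = n1 + n2 - 2`, matching the "df = 16" reported for 9 + 9
#' observations) is transformed through the standard curve, so the interval
#' is asymmetric on the percent scale.
#'
#' @param samples A [qpcr_sample()] or list of them.
#' @param reference The reference [qpcr_sample()].
#' @param curve A [standard_curve()] with negative slope.
#' @param confidence Confidence level (default 0.95).
#' @return `data.frame` with one row per sample: `id`, `percent`,
#'   `ci_lower`, `ci_upper`, `df`.
#' @export
quantify_relative <- function(samples, reference, curve, confidence = 0.95) {
  stopifnot(inherits(reference, "qpcr_sample"))
  if (curve$slope >= 0) stop("standard curve slope must be negative")
  if (inherits(samples, "qpcr_sample")) samples <- list(samples)
  n2 <- length(reference$ct_values)
  if (n2 > 1L && stats::sd(reference$ct_values) == 0) {
    warning("reference replicates have zero variance")
  }
  ref_ct <- mean(reference$ct_values)
  rows <- lapply(samples, function(s) {
    stopifnot(inherits(s, "qpcr_sample"))
    n1 <- length(s$ct_values)
    d <- mean(s$ct_values) - ref_ct
    percent <- 100 * 10^(d / curve$slope)
    if (n1 >= 2L && n2 >= 2L) {
      sp <- sqrt(((n1 - 1) * stats::var(s$ct_values) +
                    (n2 - 1) * stats::var(reference$ct_values)) /
                   (n1 + n2 - 2))
      se <- sp * sqrt(1 / n1 + 1 / n2)
      df <- n1 + n2 - 2
      tq <- stats::qt(1 - (1 - confidence) / 2, df)
      bounds <- 100 * 10^((d + c(1, -1) * tq * se) / curve$slope)
      data.frame(id = s$id, percent = percent,
                 ci_lower = min(bounds), ci_upper = max(bounds), df = df)
    } else {
      data.frame(id = s$id, percent = percent,
                 ci_lower = NA_real_, ci_upper = NA_real_, df = NA_integer_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
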