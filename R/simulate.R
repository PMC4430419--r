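#' Phenotype parameters for the network simulator
#'
#' Bundles the generator settings for one mitochondrial-network phenotype:
#' `"tubular"` draws long, persistent curvilinear filaments (the elongated
#' hyperfused networks some drugs induce), `"fragmented"` draws small
#' ellipse/disk blobs (fission phenotype), and `"control"` draws a
#' semi-aligned network of filaments of intermediate length. Filaments are
#' 2-D persistent random walks dilated to `width_px`; blobs are rasterized
#' rotated ellipses.
#'
#' @param phenotype `"control"`, `"tubular"` or `"fragmented"`.
#' @param n_structures Number of structures drawn (>= 0).
#' @param filament_length_mean,filament_length_sd Filament length
#'   distribution (pixels; truncated below at 5).
#' @param persistence Curvature memory in `[0, 1]`; 1 = straight.
#' @param blob_radius_mean,blob_radius_sd Blob radius distribution
#'   (pixels; truncated below at 2.2 so blobs survive the > 12 px filter).
#' @param width_px Filament thickness (dilation disc diameter ~ width + 1).
#' @param psf_sigma_px Gaussian blur emulating the point-spread function.
#' @param snr Peak-signal to noise ratio (> 0); total noise is an equal
#'   split of Poisson shot noise and Gaussian read noise.
#' @param background_level Background gray value.
#' @param signal_amplitude Peak structure intensity above background.
#' @param n_defocused_slices Number of deliberately defocused slices added
#'   at the stack ends (they fail the variance > 1 triage criterion).
#' @param n_focus_slices Number of in-focus slices (focus weights peak at
#'   the middle slice).
#' @param img_size Image edge length in pixels (square frames).
#' @param orientation_jitter SD (radians) of per-structure orientation
#'   around a shared image-level axis; small values give the semi-aligned
#'   look of body-wall muscle.
#' @param pixel_size_um,bit_depth Stack metadata.
#' @return Named list of class `phenotype_params`.
#' @export
phenotype_params <- function(phenotype = c("control", "tubular", "fragmented"),
                             n_structures = NULL,
                             filament_length_mean = NULL,
                             filament_length_sd = NULL,
                             persistence = NULL,
                             blob_radius_mean = 3,
                             blob_radius_sd = 0.8,
                             width_px = 2,
                             psf_sigma_px = 1,
                             snr = 10,
                             background_level = 20,
                             signal_amplitude = 160,
                             n_defocused_slices = 2,
                             n_focus_slices = 3,
                             img_size = 160,
                             orientation_jitter = NULL,
                             pixel_size_um = 0.2,
                             bit_depth = 8) {
  phenotype <- match.arg(phenotype)
  defaults <- switch(phenotype,
    control = list(n_structures = 30, filament_length_mean = 25,
                   filament_length_sd = 8, persistence = 0.75,
                   orientation_jitter = 0.35),
    tubular = list(n_structures = 20, filament_length_mean = 80,
                   filament_length_sd = 20, persistence = 0.92,
                   orientation_jitter = 0.7),
    fragmented = list(n_structures = 45, filament_length_mean = 8,
                      filament_length_sd = 2, persistence = 0.5,
                      orientation_jitter = pi))
  p <- list(phenotype = phenotype,
            n_structures = n_structures %||% defaults$n_structures,
            filament_length_mean = filament_length_mean %||% defaults$filament_length_mean,
            filament_length_sd = filament_length_sd %||% defaults$filament_length_sd,
            persistence = persistence %||% defaults$persistence,
            blob_radius_mean = blob_radius_mean,
            blob_radius_sd = blob_radius_sd,
            width_px = width_px, psf_sigma_px = psf_sigma_px, snr = snr,
            background_level = background_level,
            signal_amplitude = signal_amplitude,
            n_defocused_slices = n_defocused_slices,
            n_focus_slices = n_focus_slices,
            img_size = img_size,
            orientation_jitter = orientation_jitter %||% defaults$orientation_jitter,
            pixel_size_um = pixel_size_um, bit_depth = bit_depth)
  if (p$n_structures < 0) stop("`n_structures` must be >= 0")
  if (p$snr <= 0) stop("`snr` must be > 0")
  if (p$img_size < 16) stop("non-positive or degenerate image dimensions")
  structure(p, class = "phenotype_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rasterize one structure; returns a 2-column (row, col) coordinate matrix.
.draw_structure <- function(p, base_angle) {
  sz <- p$img_size
  margin <- 6
  if (p$phenotype == "fragmented") {
    r <- max(2.2, stats::rnorm(1, p$blob_radius_mean, p$blob_radius_sd))
    ecc <- stats::runif(1, 1, 1.3)
    phi <- stats::runif(1, 0, pi)
    cr <- stats::runif(1, margin + r, sz - margin - r)
    cc <- stats::runif(1, margin + r, sz - margin - r)
    a <- r * ecc; b <- r / ecc
    half <- ceiling(a) + 1L
    g <- expand.grid(dr = -half:half, dc = -half:half)
    u <- g$dr * cos(phi) + g$dc * sin(phi)
    v <- -g$dr * sin(phi) + g$dc * cos(phi)
    keep <- (u / a)^2 + (v / b)^2 <= 1
    rc <- cbind(round(cr) + g$dr[keep], round(cc) + g$dc[keep])
    info <- list(type = "blob", radius = r, ecc = ecc, angle = phi)
  } else {
    len <- max(5, round(stats::rnorm(1, p$filament_length_mean,
                                     p$filament_length_sd)))
    theta <- base_angle + stats::rnorm(1, 0, p$orientation_jitter)
    pos <- c(stats::runif(1, margin, sz - margin),
             stats::runif(1, margin, sz - margin))
    pts <- matrix(0, len + 1L, 2L)
    pts[1, ] <- pos
    for (i in seq_len(len)) {
      theta <- theta + (1 - p$persistence) * stats::rnorm(1, 0, 0.8)
      pos <- pos + c(cos(theta), sin(theta))
      pos <- pmin(pmax(pos, margin / 2), sz - margin / 2)
      pts[i + 1L, ] <- pos
    }
    rc <- unique(round(pts))
    # dilate the center line to the tubule width
    half <- max(0L, floor(p$width_px / 2))
    if (half > 0L) {
      offs <- expand.grid(dr = -half:half, dc = -half:half)
      offs <- offs[offs$dr^2 + offs$dc^2 <= half^2 + 0.5, ]
      rc <- unique(rbind(
        rc[rep(seq_len(nrow(rc)), each = nrow(offs)), , drop = FALSE] +
          as.matrix(offs[rep(seq_len(nrow(offs)), times = nrow(rc)), ])))
    }
    info <- list(type = "filament", length = len, angle = theta)
  }
  rc <- rc[rc[, 1] >= 1 & rc[, 1] <= sz & rc[, 2] >= 1 & rc[, 2] <= sz, ,
           drop = FALSE]
  list(rc = rc, info = info)
}

#' Simulate a microscopy stack of a mitochondrial network with ground truth
#'
#' Renders `n_structures` phenotype-specific structures into a clean 2-D
#' scene, spreads it over `n_focus_slices` in-focus slices (triangular focus
#' weights), blurs with a Gaussian point-spread function, and adds Poisson
#' shot noise plus Gaussian read noise scaled so the peak-signal to total
#' noise ratio equals `snr`. `n_defocused_slices` heavily blurred,
#' near-uniform slices are appended at the stack ends so the variance
#' triage criterion has something to reject. Ground-truth labels are the
#' 8-connected components of the union of rendered structures (structures
#' that touch or cross merge into one true object).
#'
#' @param params A [phenotype_params()].
#' @param seed Integer seed; identical seed and parameters give
#'   bit-identical output.
#' @return List with `stack` (an [image_stack()]; defocused/in-focus slice
#'   indices in `metadata`) and `truth` (list: `mask`, `labels`,
#'   `n_objects`, `per_structure`, `in_focus_slices`, `defocused_slices`).
#' @export
simulate_network_stack <- function(params, seed = 1) {
  stopifnot(inherits(params, "phenotype_params"))
  withr::with_seed(seed, {
    p <- params
    sz <- p$img_size
    max_gray <- 2^p$bit_depth - 1
    base_angle <- stats::runif(1, 0, pi)
    mask <- matrix(FALSE, sz, sz)
    per_structure <- vector("list", p$n_structures)
    if (p$n_structures > 0) {
      for (s in seq_len(p$n_structures)) {
        st <- .draw_structure(p, base_angle)
        mask[st$rc] <- TRUE
        per_structure[[s]] <- st$info
      }
    }
    labels <- .label_components(mask, connectivity = 8)
    clean <- matrix(0, sz, sz)
    clean[mask] <- p$signal_amplitude
    clean_blur <- as.matrix(EBImage::gblur(clean, sigma = p$psf_sigma_px))
    sigma_tot <- p$signal_amplitude / p$snr
    gain <- sigma_tot^2 / (2 * p$signal_amplitude)  # shot-noise var = gain * clean
    wts <- if (p$n_focus_slices == 1L) 1 else c(0.45, 1, 0.45)[seq_len(p$n_focus_slices)]
    wts[is.na(wts)] <- 0.3
    n_total <- p$n_focus_slices + p$n_defocused_slices
    vox <- array(0, c(n_total, sz, sz))
    n_lead <- ceiling(p$n_defocused_slices / 2)
    defoc_idx <- c(seq_len(n_lead),
                   n_total - seq_len(p$n_defocused_slices - n_lead) + 1L)
    defoc_idx <- sort(defoc_idx[seq_len(p$n_defocused_slices)])
    focus_idx <- setdiff(seq_len(n_total), defoc_idx)
    for (i in seq_along(focus_idx)) {
      sig <- p$background_level + wts[i] * clean_blur
      shot <- if (gain > 0) gain * matrix(stats::rpois(sz * sz, sig / gain), sz, sz) - sig else 0
      read <- matrix(stats::rnorm(sz * sz, 0, sigma_tot / sqrt(2)), sz, sz)
      vox[focus_idx[i], , ] <- pmin(pmax(round(sig + shot + read), 0), max_gray)
    }
    if (p$n_defocused_slices > 0) {
      heavy <- as.matrix(EBImage::gblur(clean, sigma = 15))
      for (i in defoc_idx) {
        sl <- p$background_level + 0.02 * heavy +
          matrix(stats::rnorm(sz * sz, 0, 0.2), sz, sz)
        vox[i, , ] <- pmin(pmax(round(sl), 0), max_gray)
      }
    }
    stack <- image_stack(vox, pixel_size_um = p$pixel_size_um,
                         bit_depth = p$bit_depth,
                         metadata = list(phenotype = p$phenotype,
                                         seed = seed,
                                         in_focus_slices = focus_idx,
                                         defocused_slices = defoc_idx))
    truth <- list(mask = mask, labels = labels,
                  n_objects = max(labels),
                  per_structure = per_structure,
                  in_focus_slices = focus_idx,
                  defocused_slices = defoc_idx)
    list(stack = stack, truth = truth)
  })
}

#' Simulate a feature table with known class structure
#'
#' Draws `n_per_class` feature records per class as
#' `baseline + class_effect + Gaussian(0, noise_sd)` per metric, tagging
#' each row with its generating class; a direct fixture for the clustering
#' stage.
#'
#' @param n_per_class Rows per class (>= 2).
#' @param class_effects Named list (>= 2 classes) of named numeric vectors
#'   of per-metric mean shifts; metrics not mentioned shift by 0.
#' @param noise_sd Per-metric noise SD: scalar or named vector (>= 0).
#' @param seed Integer seed.
#' @param baseline Named baseline values for the ten metrics.
#' @return `data.frame` with `image_id`, `Condition`, the metric columns
#'   and `NObjects` (fixed at 1).
#' @export
simulate_feature_table <- function(n_per_class, class_effects, noise_sd = 0.5,
                                   seed = 1,
                                   baseline = c(Mean = 120, Area = 60, AR = 2,
                                                Feret = 12, Solidity = 0.9,
                                                Circ = 0.6, Round = 0.55,
                                                Entropy = 2.5, Contrast = 40,
                                                Correlation = 0.8)) {
  if (length(class_effects) < 2L) stop("need at least 2 classes")
  if (n_per_class < 2L) stop("`n_per_class` must be >= 2")
  if (any(noise_sd < 0)) stop("`noise_sd` must be >= 0")
  metrics <- names(baseline)
  sds <- if (length(noise_sd) == 1L) {
    stats::setNames(rep(noise_sd, length(metrics)), metrics)
  } else {
    noise_sd[metrics]
  }
  withr::with_seed(seed, {
    rows <- list()
    for (cl in names(class_effects)) {
      eff <- stats::setNames(rep(0, length(metrics)), metrics)
      given <- class_effects[[cl]]
      eff[names(given)] <- given
      for (i in seq_len(n_per_class)) {
        vals <- baseline + eff + stats::rnorm(length(metrics), 0, sds)
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = sprintf("%s_%02d", cl, i), Condition = cl,
          as.data.frame(as.list(vals)), NObjects = 1L,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a qPCR run from a standard curve
#'
#' Generates replicate Ct values
#' `ct = slope * log10(copies) + intercept + Gaussian(0, ct_noise_sd)` for
#' each true copy number.
#'
#' @param true_copies Vector of true template copy numbers (> 0).
#' @param curve A [standard_curve()].
#' @param ct_noise_sd Ct noise SD in cycles (>= 0).
#' @param replicates Replicates per copy number.
#' @param seed Integer seed.
#' @return `data.frame` with `sample`, `copies_true`, `replicate`, `ct`.
#' @export
simulate_qpcr_run <- function(true_copies, curve, ct_noise_sd = 0.2,
                              replicates = 3, seed = 1) {
  if (any(true_copies <= 0)) stop("copy numbers must be > 0")
  stopifnot(inherits(curve, "standard_curve"))
  withr::with_seed(seed, {
    n <- length(true_copies)
    out <- expand.grid(replicate = seq_len(replicates),
                       sample = seq_len(n))[, 2:1]
    out$copies_true <- true_copies[out$sample]
    out$ct <- curve$slope * log10(out$copies_true) + curve$intercept +
      stats::rnorm(nrow(out), 0, ct_noise_sd)
    out[, c("sample", "copies_true", "replicate", "ct")]
  })
}

#' Simulate a dissolved-oxygen consumption trace
#'
#' Linear O2 decline at `-rate` with optional Gaussian noise and an
#' optional nonlinear initial equilibration transient (exponential decay
#' over the first `equil_frac` of the trace), as seen before a respirometer
#' chamber settles.
#'
#' @param rate Consumption rate (concentration units per minute, >= 0).
#' @param duration_min Trace duration in minutes (> 0; default 10).
#' @param sampling_hz Samples per second (default 1).
#' @param noise_sd Measurement noise SD (default 0).
#' @param o2_start Initial O2 concentration (default 21).
#' @param equilibration Add the initial transient? (default `FALSE`).
#' @param equil_frac Fraction of the trace affected by the transient.
#' @param equil_amp Amplitude of the transient (concentration units).
#' @param seed Integer seed.
#' @return `data.frame` with `time_min` and `o2`.
#' @export
simulate_o2_trace <- function(rate, duration_min = 10, sampling_hz = 1,
                              noise_sd = 0, o2_start = 21,
                              equilibration = FALSE, equil_frac = 0.1,
                              equil_amp = 1.5, seed = 1) {
  if (duration_min <= 0) stop("`duration_min` must be > 0")
  withr::with_seed(seed, {
    t <- seq(0, duration_min, by = 1 / (60 * sampling_hz))
    o2 <- o2_start - rate * t
    if (equilibration) {
      tau <- equil_frac * duration_min / 3
      o2 <- o2 + equil_amp * exp(-t / tau)
    }
    if (noise_sd > 0) o2 <- o2 + stats::rnorm(length(t), 0, noise_sd)
    data.frame(time_min = t, o2 = o2)
  })
}
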