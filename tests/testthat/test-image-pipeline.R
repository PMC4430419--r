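test_that("slice triage keeps exactly the informative slices", {
  # uniform slice: statistic 0, rejected; half 0 / half 200: variance 10000
  vox <- array(0, c(3, 10, 10))
  vox[2, , 1:5] <- 200
  vox[3, , ] <- matrix(runif(100, 0, 255), 10, 10)
  st <- image_stack(vox)
  tr <- triage_slices(st)
  qc <- tr$metadata$qc
  expect_equal(qc$statistic[1], 0)
  expect_equal(qc$statistic[2], 10000)
  expect_identical(qc$retained, c(2L, 3L))
  expect_equal(n_slices(tr), 2)

  # all-uniform stack fails loudly rather than returning an empty stack
  expect_error(triage_slices(image_stack(array(7, c(2, 5, 5)))),
               "empty after triage")

  # synthetic stack: exactly the generator's defocused slices are dropped
  sim <- simulate_network_stack(phenotype_params("fragmented"), seed = 2)
  tr2 <- triage_slices(sim$stack)
  expect_identical(tr2$metadata$qc$retained, as.integer(sim$truth$in_focus_slices))
})

test_that("maximum projection equals the per-pixel brute-force maximum", {
  one <- image_stack(matrix(1:12, 3, 4))
  expect_equal(unclass(max_project(one))[1:3, 1:4], matrix(1:12, 3, 4))

  set.seed(42)
  vox <- array(sample(0:255, 48, replace = TRUE), c(3, 4, 4))
  proj <- max_project(image_stack(vox))
  for (r in 1:4) for (c in 1:4) {
    expect_equal(proj[r, c], max(vox[, r, c]))
  }

  # a pointwise-dominating slice is returned unchanged
  vox2 <- array(0, c(2, 5, 5))
  vox2[1, , ] <- 10; vox2[2, , ] <- matrix(20 + 1:25, 5, 5)
  expect_equal(unclass(max_project(image_stack(vox2)))[1:5, 1:5],
               matrix(20 + 1:25, 5, 5))
})

test_that("rolling-ball background subtraction has the opening's properties", {
  const <- matrix(50, 40, 40)
  expect_true(all(subtract_background(const) == 0))

  # single bright pixel survives: the ball cannot fit into a 1-px peak
  spike <- matrix(0, 40, 40); spike[20, 20] <- 180
  out <- subtract_background(spike, ball_radius_px = 15)
  # the hemispherical element leaves a sub-0.1% discretization residue
  expect_equal(out[20, 20], 180, tolerance = 1e-3)
  expect_true(all(out[-((20 - 1) * 40 + 20)] == 0))

  # shift invariance and bounds on a structured image
  set.seed(7)
  img <- matrix(runif(1600, 0, 100), 40, 40)
  a <- subtract_background(img)
  b <- subtract_background(img + 30)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(a >= 0) && all(a <= img))

  expect_warning(subtract_background(matrix(1:25 + 0, 5, 5), 15), "extent")
  expect_error(subtract_background(img, 0.5), "radius")
})

test_that("local contrast enhancement respects range and improves separation", {
  const <- matrix(80, 30, 30)
  expect_true(all(enhance_local_contrast(const) == 80))

  set.seed(1)
  img <- matrix(runif(90 * 90, 0, 255), 90, 90)
  out <- enhance_local_contrast(img)
  expect_true(all(out >= 0) && all(out <= 255))

  expect_warning(enhance_local_contrast(img[1:10, 1:10], block_size_px = 15),
                 "global equalization")
  expect_error(enhance_local_contrast(img, block_size_px = 1), "block_size")

  # a low-contrast tubule image: Otsu inter-class variance does not decrease
  otsu_sep <- function(x) {
    x <- round(x); best <- 0
    for (t in 1:254) {
      w0 <- mean(x <= t); w1 <- 1 - w0
      if (w0 > 0 && w1 > 0) {
        d <- (mean(x[x <= t]) - mean(x[x > t]))^2 * w0 * w1
        if (d > best) best <- d
      }
    }
    best
  }
  sim <- simulate_network_stack(phenotype_params("tubular", snr = 4), seed = 6)
  proj <- max_project(triage_slices(sim$stack))
  low <- proj * 0.3  # compress dynamic range
  expect_gte(otsu_sep(enhance_local_contrast(low)), otsu_sep(low))
})

test_that("multi-scale Laplacian responds at blob centers", {
  expect_true(all(multiscale_laplacian(matrix(5, 20, 20)) == 0))
  expect_error(multiscale_laplacian(matrix(1:4, 2, 2), numeric(0)), "scale")

  blob <- gaussian_blob(41, c(21, 21), sigma = 2)
  resp <- multiscale_laplacian(blob, scales_px = c(1, 2, 4))
  expect_equal(which.max(resp), (21 - 1) * 41 + 21)

  # two blobs of different sizes: both are local maxima of the multi-scale
  # response, while the small-scale response alone underweights the big blob
  two <- gaussian_blob(81, c(20, 20), sigma = 2) +
    gaussian_blob(81, c(60, 60), sigma = 6)
  multi <- multiscale_laplacian(two, scales_px = c(1, 2, 4, 6))
  is_local_max <- function(m, r, c, rad = 3) {
    m[r, c] == max(m[(r - rad):(r + rad), (c - rad):(c + rad)])
  }
  expect_true(is_local_max(multi, 20, 20))
  expect_true(is_local_max(multi, 60, 60))
  single <- multiscale_laplacian(two, scales_px = 1)
  expect_gt(multi[60, 60] / multi[20, 20], single[60, 60] / single[20, 20])
})

test_that("Yen threshold maximizes the criterion and handles degeneracy", {
  # two-valued image: threshold falls between the values, mask = bright side
  img <- matrix(10, 10, 10); img[3:6, 3:6] <- 200
  res <- binarize_yen(img)
  expect_gte(res$threshold, 10)
  expect_lt(res$threshold, 200)
  expect_identical(res$mask, img == 200)

  # intensity inversion flips the mask
  inv <- binarize_yen(255 - img)
  expect_identical(inv$mask, !res$mask)

  expect_error(yen_threshold(matrix(4, 3, 3)), "degenerate")

  # oracle: the returned threshold attains the exhaustive-search criterion
  # maximum on 100 random 8-bit images
  set.seed(99)
  for (i in 1:100) {
    x <- matrix(sample(0:255, 400, replace = TRUE, prob = runif(256)), 20, 20)
    thr <- yen_threshold(x)
    breaks <- seq(min(x), max(x), length.out = 257)
    idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1), 256)
    p <- tabulate(idx, nbins = 256) / length(x)
    crit <- oracle_yen_criterion(p)
    centers <- (breaks[-1] + breaks[-257]) / 2
    expect_equal(thr, centers[which.max(crit)])
  }
})

test_that("object extraction filters by strict size and honors connectivity", {
  mask <- matrix(FALSE, 20, 40)
  mask[2:3, 2:6] <- TRUE            # 10 px: removed at min 12
  mask[10:13, 10:14] <- TRUE        # 20 px: kept
  obj <- extract_objects(mask, min_size_px = 12)
  expect_equal(obj$n_objects, 1)
  expect_equal(obj$sizes, 20L)

  # a component of exactly 12 pixels is removed (strictly larger survives)
  m12 <- matrix(FALSE, 10, 10); m12[3:6, 3:5] <- TRUE
  expect_equal(extract_objects(m12, min_size_px = 12)$n_objects, 0)
  expect_equal(extract_objects(m12, min_size_px = 11)$n_objects, 1)

  # diagonal chain: one object at 8-connectivity, n at 4-connectivity
  diagm <- matrix(FALSE, 8, 8); diag(diagm) <- TRUE
  expect_equal(extract_objects(diagm, min_size_px = 0, connectivity = 8)$n_objects, 1)
  expect_equal(extract_objects(diagm, min_size_px = 0, connectivity = 4)$n_objects, 8)

  expect_error(extract_objects(matrix(2, 3, 3)), "binary")

  # idempotence: re-extracting from the produced mask reproduces the labels
  again <- extract_objects(obj$label_image > 0, min_size_px = 12)
  expect_identical(again$label_image, obj$label_image)
})

test_that("full pipeline recovers ground truth and is deterministic", {
  # blank stack: zero objects
  blank <- simulate_network_stack(phenotype_params("control", n_structures = 0),
                                  seed = 4)
  expect_equal(run_pipeline(blank$stack)$objects$n_objects, 0)

  # fragmented: object count within 10% of ground truth (median over seeds)
  rel_err <- sapply(1:5, function(s) {
    sim <- simulate_network_stack(phenotype_params("fragmented"), seed = s)
    res <- run_pipeline(sim$stack)
    abs(res$objects$n_objects - sim$truth$n_objects) / sim$truth$n_objects
  })
  expect_lte(median(rel_err), 0.10)

  # determinism of the whole composition
  sim <- simulate_network_stack(phenotype_params("control"), seed = 8)
  r1 <- run_pipeline(sim$stack)
  r2 <- run_pipeline(sim$stack)
  expect_identical(r1$objects$label_image, r2$objects$label_image)
  expect_identical(r1$threshold, r2$threshold)
})
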