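# Independent brute-force oracles used across the suite. These deliberately
# take the slow, direct route (explicit loops, naive enumeration) so they
# share no code with the implementation they check.

# Yen's maximum-correlation criterion evaluated directly from a histogram of
# bin probabilities p (length N); returns the criterion for every split
# t = 1..N-1 (foreground = bins 1..t).
oracle_yen_criterion <- function(p) {
  N <- length(p)
  crit <- numeric(N - 1)
  for (t in seq_len(N - 1)) {
    P1 <- sum(p[1:t]); P2 <- 1 - P1
    S1 <- sum(p[1:t]^2); S2 <- sum(p[(t + 1):N]^2)
    crit[t] <- if (P1 > 0 && P2 > 0 && S1 > 0 && S2 > 0) {
      2 * log(P1 * P2) - log(S1 * S2)
    } else {
      -Inf
    }
  }
  crit
}

# GLCM by explicit double-loop pair counting.
oracle_glcm <- function(img, offset, n_levels, max_gray) {
  q <- pmin(floor(img / (max_gray + 1) * n_levels), n_levels - 1)
  counts <- matrix(0, n_levels, n_levels)
  dr <- offset[1]; dc <- offset[2]
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
        counts[q[r, c] + 1, q[r2, c2] + 1] <- counts[q[r, c] + 1, q[r2, c2] + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

# Texture features by direct summation over every matrix cell.
oracle_glcm_features <- function(P) {
  N <- nrow(P)
  ent <- 0; con <- 0
  for (i in 1:N) for (j in 1:N) {
    if (P[i, j] > 0) ent <- ent - P[i, j] * log(P[i, j])
    con <- con + P[i, j] * (i - j)^2
  }
  mu_i <- 0; mu_j <- 0
  for (i in 1:N) for (j in 1:N) {
    mu_i <- mu_i + (i - 1) * P[i, j]
    mu_j <- mu_j + (j - 1) * P[i, j]
  }
  v_i <- 0; v_j <- 0; cor_ <- 0
  for (i in 1:N) for (j in 1:N) {
    v_i <- v_i + (i - 1 - mu_i)^2 * P[i, j]
    v_j <- v_j + (j - 1 - mu_j)^2 * P[i, j]
  }
  for (i in 1:N) for (j in 1:N) {
    cor_ <- cor_ + P[i, j] * (i - 1 - mu_i) * (j - 1 - mu_j)
  }
  list(entropy = ent, contrast = con,
       correlation = if (v_i > 0 && v_j > 0) cor_ / sqrt(v_i * v_j) else NaN)
}

# Feret diameter by O(n^2) scan over ALL object pixel centers (a superset of
# boundary pixels, attaining the same maximum).
oracle_feret <- function(rc) {
  best <- 0
  n <- nrow(rc)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((rc[i, ] - rc[j, ])^2))
      if (d > best) best <- d
    }
  }
  best
}

# UPGMA by O(n^3) agglomeration over explicit point sets; returns the
# cophenetic distance matrix (merge height between every pair of points).
oracle_upgma_cophenetic <- function(X) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        d <- mean(D[clusters[[a]], clusters[[b]], drop = FALSE])
        if (d < best[1]) best <- c(d, a, b)
      }
    }
    for (i in clusters[[best[2]]]) for (j in clusters[[best[3]]]) {
      coph[i, j] <- best[1]; coph[j, i] <- best[1]
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  coph
}

# Rasterized disk / axis-aligned ellipse pixel coordinates (centers within
# the analytic shape).
raster_disk <- function(r, center = c(r + 5, r + 5)) {
  g <- expand.grid(row = 1:(2 * r + 10), col = 1:(2 * r + 10))
  as.matrix(g[(g$row - center[1])^2 + (g$col - center[2])^2 <= r^2, ])
}

raster_ellipse <- function(a, b, center = c(a + 5, a + 5)) {
  sz <- 2 * max(a, b) + 10
  g <- expand.grid(row = 1:sz, col = 1:sz)
  keep <- ((g$row - center[1]) / b)^2 + ((g$col - center[2]) / a)^2 <= 1
  as.matrix(g[keep, ])
}

# Label matrix for a coordinate set inside an otherwise empty frame.
coords_to_labels <- function(rc, nrow_, ncol_) {
  lab <- matrix(0L, nrow_, ncol_)
  lab[rc] <- 1L
  lab
}

# Gaussian blob image (for Laplacian response tests).
gaussian_blob <- function(size, center, sigma, amplitude = 100) {
  g <- expand.grid(r = 1:size, c = 1:size)
  v <- amplitude * exp(-((g$r - center[1])^2 + (g$c - center[2])^2) / (2 * sigma^2))
  matrix(v, size, size)
}
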