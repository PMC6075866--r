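# Shared fixtures and independent oracles. Everything is generated in code
# at test time; no binary fixtures.

# Small phantom for fast segmentation/quantification tests.
small_phantom_config <- function(n = 80, canvas = 240L, dropout_rate = 0,
                                 ...) {
  phantom_config(n_cells = as.integer(n), canvas = c(canvas, canvas),
                 dropout = list(rate = dropout_rate, cycles = 2:10,
                                density_bias = 1, bias_radius = 30),
                 ...)
}

# Noise-free, artifact-free acquisition over a single 240 px tile.
clean_acq <- function(n_cycles = 1L, offsets = NULL, tile = 240L,
                      grid = c(rows = 1L, cols = 1L), ...) {
  if (is.null(offsets)) offsets <- matrix(0, n_cycles, 3)
  acquisition_model(n_cycles = n_cycles, offsets = offsets,
                    grid = grid, tile = c(width = tile, height = tile),
                    shading = list(amplitude = 0),
                    af = list(amplitude = 0, decay = 1),
                    noise = list(photons_per_count = 0, read_sd = 0), ...)
}

# Render a phantom into an assembled, artifact-free stack with identity
# transforms (bypasses stitching; used to test segmentation in isolation).
clean_stack <- function(phantom, acq, seed = 1L) {
  ts <- render_cycles(phantom, acq, seed = seed)
  mosaics <- lapply(ts$ideal, function(cyc) cyc)
  transforms <- replicate(length(mosaics), rigid_transform(), simplify = FALSE)
  assemble_stack(mosaics, transforms)
}

# Brute-force integer-lag cross-correlation peak. Returns the shift t
# (dy, dx) such that b best matches a displaced by t.
brute_xcorr_peak <- function(a, b, max_lag = 12) {
  best <- c(-Inf, NA, NA)
  h <- nrow(a); w <- ncol(a)
  for (dy in -max_lag:max_lag) for (dx in -max_lag:max_lag) {
    ya <- max(1, 1 + dy):min(h, h + dy); xa <- max(1, 1 + dx):min(w, w + dx)
    yb <- ya - dy; xb <- xa - dx
    v <- sum(a[ya, xa] * b[yb, xb])
    if (v > best[1]) best <- c(v, dy, dx)
  }
  c(dy = -best[2], dx = -best[3])
}

# Align mixture components to reference labels over all permutations
# (small k only) minimizing total mean distance; returns the permutation.
best_permutation <- function(est_means, true_means) {
  k <- nrow(true_means)
  perms <- matrix(unlist(combinat_perms(seq_len(k))), ncol = k, byrow = TRUE)
  cost <- apply(perms, 1, function(p)
    sum((est_means[p, , drop = FALSE] - true_means)^2))
  perms[which.min(cost), ]
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# Adjusted Rand index between two labelings (independent of mclust).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Match segmented centroids to phantom truth: a truth cell is recovered if
# some centroid lies within its radius; precision counts matched centroids.
segmentation_scores <- function(truth, celltable) {
  d2 <- outer(truth$x, celltable$centroid_x, "-")^2 +
        outer(truth$y, celltable$centroid_y, "-")^2
  nn <- apply(d2, 1, which.min)
  hit <- sqrt(d2[cbind(seq_len(nrow(truth)), nn)]) <= truth$radius
  list(recall = mean(hit),
       precision = length(unique(nn[hit])) / nrow(celltable))
}

# Re-export the package's seeded-evaluation helper for test fixtures
# (lazy evaluation keeps the seeding semantics).
with_seed <- function(seed, code) cycifer:::with_seed(seed, code)
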