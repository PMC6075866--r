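# Spatial analysis: field grids, Shannon-entropy heterogeneity, marker
# gating, tumor/stroma region assignment, kNN density and co-occurrence,
# bootstrapped counts.

#' Partition cells into a regular field grid
#'
#' Fields tile the mosaic without overlap; a cell at an exact boundary
#' belongs to the higher-index field (floor convention).
#'
#' @param celltable CellTable with `centroid_x`, `centroid_y`.
#' @param field_w,field_h field size in px.
#' @return list of class `FieldGrid`: `map` (cell_id, field_id, row, col),
#'   `counts` (per-field data.frame), `field_size`.
#' @export
grid_fields <- function(celltable, field_w, field_h) {
  stopifnot(field_w > 0, field_h > 0)
  row <- floor(celltable$centroid_y / field_h)
  col <- floor(celltable$centroid_x / field_w)
  fid <- sprintf("f%d_%d", row, col)
  counts <- as.data.frame(table(field_id = fid), stringsAsFactors = FALSE)
  names(counts)[2] <- "n_cells"
  structure(list(map = data.frame(cell_id = celltable$cell_id,
                                  field_id = fid, row = row, col = col,
                                  stringsAsFactors = FALSE),
                 counts = counts,
                 field_size = c(w = field_w, h = field_h)),
            class = "FieldGrid")
}

#' Non-parametric Shannon entropy of a field's intensities
#'
#' Samples `n_sample` cells without replacement, rescales their intensity
#' vector to unit L2 norm so that the squared entries form a probability
#' vector, and computes `E = -sum(s_i^2 * ln(s_i^2))` (nats, with
#' `0 ln 0 = 0`). Uniform intensities give the maximum `ln(n_sample)`; a
#' single expressing cell gives 0.
#'
#' @param intensities per-cell intensities of one channel in one field;
#'   must number more than `n_sample` (fields at or below that are excluded
#'   from entropy maps).
#' @param n_sample cells sampled per field (default 1000).
#' @param seed integer seed for the subsample.
#' @return entropy in nats (`NA` with a warning if all intensities are 0).
#' @export
field_entropy <- function(intensities, n_sample = 1000L, seed = 1L) {
  if (length(intensities) <= n_sample)
    stop("field has ", length(intensities), " cells; more than ", n_sample,
         " are required")
  x <- with_seed(seed, sample(intensities, n_sample))
  shannon_entropy(x)
}

#' Shannon entropy of an L2-normalized intensity vector
#'
#' The workhorse behind [field_entropy()]: rescales `values` to unit L2
#' norm and returns `-sum(s_i^2 * ln(s_i^2))` with `0 ln 0 = 0`.
#'
#' @param values non-negative intensities.
#' @return entropy in nats, in `[0, ln(length(values))]`; `NA` with a
#'   warning when all values are zero.
#' @export
shannon_entropy <- function(values) {
  if (all(values == 0)) {
    warning("all intensities are zero; entropy undefined")
    return(NA_real_)
  }
  p <- (values / sqrt(sum(values^2)))^2
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Normalize field entropies by the specimen-wide entropy
#'
#' @param field_entropies numeric vector of per-field entropies.
#' @param sample_entropy specimen-wide entropy (> 0), computed from
#'   `n_sample` cells drawn across the whole specimen.
#' @return elementwise ratio (>= 0; values may exceed 1).
#' @export
normalize_entropy <- function(field_entropies, sample_entropy) {
  stopifnot(sample_entropy > 0)
  field_entropies / sample_entropy
}

#' Per-field normalized entropy map for one channel
#'
#' @param celltable CellTable.
#' @param values per-cell intensities aligned with `celltable` rows.
#' @param fields a [grid_fields()] result.
#' @param n_sample cells sampled per field; fields with no more than this
#'   many cells are excluded.
#' @param seed integer seed.
#' @return data.frame field_id, n_cells, entropy, normalized.
#' @export
entropy_map <- function(celltable, values, fields, n_sample = 1000L,
                        seed = 1L) {
  stopifnot(length(values) == nrow(celltable))
  if (length(values) <= n_sample)
    stop("specimen has too few cells for the specimen-wide entropy")
  e_sample <- field_entropy(values, n_sample, seed)
  split_idx <- split(seq_along(values), fields$map$field_id)
  keep <- names(split_idx)[lengths(split_idx) > n_sample]
  ent <- vapply(keep, function(f)
    field_entropy(values[split_idx[[f]]], n_sample, seed), numeric(1))
  data.frame(field_id = keep,
             n_cells = lengths(split_idx)[keep],
             entropy = ent,
             normalized = normalize_entropy(ent, e_sample),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gate cells positive for a marker
#'
#' Otsu gating thresholds the log-transformed per-cell means (fluorescence
#' positivity is bimodal on a log scale); fixed gating uses a user
#' threshold on the raw scale. Composite gates (e.g. CD3+CD8+) are the
#' conjunction of single-marker gates.
#'
#' @param values per-cell marker intensities.
#' @param strategy `"otsu"` or `"fixed"`.
#' @param threshold raw-scale threshold for `strategy = "fixed"`.
#' @return logical vector, `TRUE` for positive cells.
#' @export
gate_positive <- function(values, strategy = c("otsu", "fixed"),
                          threshold = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") {
    stopifnot(!is.null(threshold))
    return(values > threshold)
  }
  thr <- otsu_threshold(log1p(values))
  log1p(values) > thr
}

#' Assign cells to tumor/stroma regions from a stromal marker
#'
#' Per-cell intensities of the stromal marker (alpha-smooth-muscle actin by
#' default) are smoothed onto a regular grid with a Gaussian kernel; an
#' Otsu split of the smoothed field labels high-marker grid cells as
#' stroma and the rest as tumor, and every cell inherits the label of its
#' grid location. A degenerate field (no contrast) leaves all cells in one
#' region with a warning.
#'
#' @param celltable CellTable.
#' @param values per-cell stromal-marker intensities.
#' @param bandwidth Gaussian kernel bandwidth in px (default 50).
#' @param grid_spacing smoothing-grid spacing in px.
#' @param width,height canvas size in px (default: from centroid extent).
#' @return list: `region` (character per cell), `mask` (grid matrix),
#'   `smoothed` field, `threshold`, `grid`.
#' @export
assign_regions <- function(celltable, values, bandwidth = 50,
                           grid_spacing = 8,
                           width = NULL, height = NULL) {
  stopifnot(length(values) == nrow(celltable))
  x <- celltable$centroid_x; y <- celltable$centroid_y
  if (is.null(width)) width <- ceiling(max(x)) + 1
  if (is.null(height)) height <- ceiling(max(y)) + 1
  gx <- seq(grid_spacing / 2, width, by = grid_spacing)
  gy <- seq(grid_spacing / 2, height, by = grid_spacing)
  Wx <- exp(-outer(gx, x, "-")^2 / (2 * bandwidth^2))
  Wy <- exp(-outer(gy, y, "-")^2 / (2 * bandwidth^2))
  num <- Wy %*% (t(Wx) * values)    # (i, j): sum_c Wy[i,c] Wx[j,c] v_c
  den <- Wy %*% t(Wx)
  smoothed <- num / pmax(den, .Machine$double.eps)
  contrast <- diff(range(smoothed)) > 1e-6 * max(abs(smoothed))
  thr <- if (contrast)
    tryCatch(otsu_threshold(as.numeric(smoothed)), error = function(e) NA_real_)
  else NA_real_
  if (!is.finite(thr) || all(smoothed > thr) || all(smoothed <= thr)) {
    warning("degenerate stromal-marker field: assigning all cells to one region")
    mask <- matrix("tumor", length(gy), length(gx))
  } else {
    mask <- matrix(ifelse(smoothed > thr, "stroma", "tumor"),
                   length(gy), length(gx))
  }
  gi <- pmin(pmax(floor(y / grid_spacing) + 1, 1), length(gy))
  gj <- pmin(pmax(floor(x / grid_spacing) + 1, 1), length(gx))
  list(region = mask[cbind(gi, gj)], mask = mask, smoothed = smoothed,
       threshold = thr,
       grid = list(x = gx, y = gy, spacing = grid_spacing))
}

#' Regular evaluation grid over a canvas
#' @param width,height canvas size in px.
#' @param spacing grid spacing in px.
#' @return data.frame of grid-point coordinates `x`, `y` (0-based px).
#' @export
make_grid <- function(width, height, spacing) {
  g <- expand.grid(x = seq(spacing / 2, width - spacing / 2, by = spacing),
                   y = seq(spacing / 2, height - spacing / 2, by = spacing))
  attr(g, "spacing") <- spacing
  g
}

#' k-nearest-neighbour spatial density estimate
#'
#' At each evaluation point, `rho = (k - 1) / (n * pi * d_k^2)` with `d_k`
#' the distance to the k-th nearest cell (the `k - 1` numerator is the
#' classical unbiasedness correction for Poisson point patterns); with
#' k = 4 and typical cell spacing this corresponds to a smoothing window
#' of roughly 10 um. `d_k` is floored at half the grid spacing to avoid
#' singularities at cell centroids.
#'
#' @param points n x 2 matrix (or data.frame) of cell centroids; n >= k.
#' @param eval_grid a [make_grid()] data.frame.
#' @param k neighbour rank (default 4).
#' @param floor_dist distance floor in px (default half the grid spacing).
#' @return `DensityField` data.frame: x, y, density; attributes `k`, `n`.
#' @export
knn_density <- function(points, eval_grid, k = 4L, floor_dist = NULL) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < k) stop("need at least k = ", k, " points (got ", n, ")")
  if (is.null(floor_dist)) {
    sp <- attr(eval_grid, "spacing")
    if (is.null(sp)) sp <- min(diff(sort(unique(eval_grid$x))))
    floor_dist <- sp / 2
  }
  d2 <- outer(eval_grid$x, pts[, 1], "-")^2 +
        outer(eval_grid$y, pts[, 2], "-")^2
  dk <- sqrt(apply(d2, 1, function(r) sort.int(r, partial = k)[k]))
  dk <- pmax(dk, floor_dist)
  out <- data.frame(x = eval_grid$x, y = eval_grid$y,
                    density = (k - 1) / (n * pi * dk^2))
  attr(out, "k") <- k; attr(out, "n") <- n
  class(out) <- c("DensityField", "data.frame")
  out
}

#' Spatial co-occurrence of two cell populations
#'
#' Within each region, each population's density is normalized to a
#' probability over the region's grid points (removing the effect of
#' absolute cell numbers per region); the co-occurrence map is the
#' pointwise product of the two probabilities. The fold enrichment
#' compares the mean co-occurrence between two named regions, and the
#' hotspot mask marks the top quantile of the product map.
#'
#' @param density_a,density_b [knn_density()] fields on the same grid.
#' @param regions region label per grid point.
#' @param fold_pair regions compared as `fold = mean(first) / mean(second)`.
#' @param hotspot_quantile product-map quantile above which a grid point is
#'   a hotspot (default 0.9, i.e. the top 10 percent).
#' @return list: `map` (x, y, region, p_a, p_b, co), `region_means`,
#'   `fold`, `hotspots` (logical per grid point).
#' @export
cooccurrence_map <- function(density_a, density_b, regions,
                             fold_pair = c("tumor", "stroma"),
                             hotspot_quantile = 0.9) {
  stopifnot(nrow(density_a) == nrow(density_b),
            length(regions) == nrow(density_a),
            all(density_a$x == density_b$x, density_a$y == density_b$y))
  p_a <- stats::ave(density_a$density, regions,
                    FUN = function(v) v / sum(v))
  p_b <- stats::ave(density_b$density, regions,
                    FUN = function(v) v / sum(v))
  co <- p_a * p_b
  region_means <- tapply(co, regions, mean)
  fold <- if (all(fold_pair %in% names(region_means)))
    unname(region_means[fold_pair[1]] / region_means[fold_pair[2]])
  else NA_real_
  list(map = data.frame(x = density_a$x, y = density_a$y, region = regions,
                        p_a = p_a, p_b = p_b, co = co),
       region_means = region_means, fold = fold,
       hotspots = co >= stats::quantile(co, hotspot_quantile))
}

#' Bootstrapped gate-positive cell counts per region
#'
#' Within each region, cells are resampled with replacement (same size)
#' `n_boot` times and gate-positive cells counted per replicate.
#'
#' @param gates named list of logical per-cell positivity vectors.
#' @param regions region label per cell.
#' @param n_boot bootstrap rounds (>= 2, default 100).
#' @param seed integer seed.
#' @return data.frame region, gate, mean, sem (sd of replicate counts
#'   divided by `sqrt(n_boot)`).
#' @export
bootstrap_counts <- function(gates, regions, n_boot = 100L, seed = 1L) {
  stopifnot(n_boot >= 2, is.list(gates), !is.null(names(gates)))
  out <- list()
  with_seed(seed, {
    for (rg in sort(unique(regions))) {
      idx <- which(regions == rg)
      reps <- matrix(0L, n_boot, length(gates))
      for (b in seq_len(n_boot)) {
        res <- sample(idx, length(idx), replace = TRUE)
        reps[b, ] <- vapply(gates, function(g) sum(g[res]), integer(1))
      }
      out[[length(out) + 1L]] <- data.frame(
        region = rg, gate = names(gates),
        mean = colMeans(reps),
        sem = apply(reps, 2, stats::sd) / sqrt(n_boot),
        stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
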