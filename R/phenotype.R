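# Single-cell feature construction and embedding: intensity transforms,
# percentile normalization, t-SNE.

#' Transform raw single-cell intensities
#'
#' Fluorescence intensities are approximately lognormal, so features are
#' variance-stabilized before clustering or embedding: `log(x + 1)` or
#' `asinh(x / cofactor)` (default cofactor 5, the common choice for
#' imaging/flow cytometry). Rows flagged `valid = FALSE` are dropped.
#'
#' @param celltable a [quantify()] CellTable, or a plain non-negative
#'   cells x features matrix.
#' @param map a [marker_channel_map()] (ignored for matrix input).
#' @param method `"asinh"` or `"log"`.
#' @param cofactor asinh cofactor.
#' @param compartment compartment to read intensities from.
#' @return numeric matrix with a `transform` attribute and `cell_id` rownames.
#' @export
transform_intensities <- function(celltable, map = NULL,
                                  method = c("asinh", "log"), cofactor = 5,
                                  compartment = "cell") {
  method <- match.arg(method)
  if (is.matrix(celltable)) {
    mat <- celltable
  } else {
    keep <- celltable$valid & stats::complete.cases(
      marker_matrix(celltable, map, compartment))
    ct <- celltable[keep, , drop = FALSE]
    mat <- marker_matrix(ct, map, compartment)
    rownames(mat) <- ct$cell_id
  }
  if (any(mat < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  out <- switch(method, log = log(mat + 1), asinh = asinh(mat / cofactor))
  attr(out, "transform") <- list(method = method, cofactor = cofactor)
  out
}

#' Percentile normalization of feature channels
#'
#' Per channel, rescales `(v - P_low) / (P_high - P_low)` and clips to
#' `[0, 1]`, aligning intensity scales between channels and samples.
#' Constant channels (P_high == P_low) are excluded with a warning.
#'
#' @param mat cells x features matrix.
#' @param p_low,p_high percentile bounds (defaults 1 and 99).
#' @return normalized matrix; excluded channels recorded in the
#'   `excluded_channels` attribute.
#' @export
normalize_channels <- function(mat, p_low = 1, p_high = 99) {
  if (nrow(mat) < 100)
    stop("normalize_channels needs >= 100 cells for stable percentiles")
  qs <- apply(mat, 2, stats::quantile, probs = c(p_low, p_high) / 100,
              names = FALSE)
  constant <- qs[2, ] == qs[1, ]
  if (any(constant))
    warning("excluding constant channel(s): ",
            paste(colnames(mat)[constant], collapse = ", "))
  keep <- which(!constant)
  out <- sapply(keep, function(j)
    pmin(pmax((mat[, j] - qs[1, j]) / (qs[2, j] - qs[1, j]), 0), 1))
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), colnames(mat)[keep]))
  attr(out, "normalization") <- list(p_low = p_low, p_high = p_high,
                                     quantiles = qs[, keep, drop = FALSE])
  attr(out, "excluded_channels") <- colnames(mat)[constant]
  out
}

#' 2-D t-SNE embedding of single-cell features
#'
#' Exact t-SNE with the classic cytometry settings: perplexity 30,
#' learning rate 500, early exaggeration 4 for the first 100 iterations.
#' Deterministic for a fixed seed (single-threaded, exact gradients).
#'
#' @param mat cells x features matrix (needs more than `3 * perplexity`
#'   cells).
#' @param perplexity t-SNE perplexity.
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations.
#' @return cells x 2 matrix of embedding coordinates.
#' @export
embed_tsne <- function(mat, perplexity = 30, seed = 1L, max_iter = 1000L) {
  if (nrow(mat) - 1 < 3 * perplexity)
    stop("too few cells for perplexity ", perplexity,
         " (need more than ", 3 * perplexity, ")")
  fit <- with_seed(seed,
    Rtsne::Rtsne(mat, dims = 2, perplexity = perplexity, theta = 0,
                 eta = 500, exaggeration_factor = 4, stop_lying_iter = 100L,
                 max_iter = max_iter, pca = FALSE, check_duplicates = FALSE,
                 num_threads = 1L))
  out <- fit$Y
  rownames(out) <- rownames(mat)
  colnames(out) <- c("tsne1", "tsne2")
  out
}

#' Per-group cluster composition
#'
#' @param assignments cluster label per cell.
#' @param groups grouping label per cell (e.g. tumor region).
#' @return matrix of within-group proportions; rows (groups) sum to 1.
#' @export
cluster_composition <- function(assignments, groups) {
  stopifnot(length(assignments) == length(groups))
  tab <- table(group = groups, cluster = assignments)
  prop <- prop.table(tab, margin = 1)
  unclass(prop)
}
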