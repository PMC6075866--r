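# Nuclear segmentation, cytoplasm-ring expansion and per-cell
# quantification. Segmentation runs once on the reference-cycle nuclear
# mosaic; the resulting regions of interest are applied to every cycle of
# the registered stack.

#' Binarize the nuclear channel
#'
#' Global Otsu threshold on the full image, followed by filling of small
#' holes and removal of objects below a minimum area.
#'
#' @param image nuclear-channel matrix (must be non-constant).
#' @param min_area remove connected foreground objects smaller than this
#'   (px, default 20).
#' @param max_hole fill background holes smaller than this (px, default 10).
#' @return logical matrix mask.
#' @export
binarize_nuclei <- function(image, min_area = 20L, max_hole = 10L) {
  if (diff(range(image)) == 0)
    stop(errorCondition("cannot threshold a constant image (no foreground)",
                        class = c("cycifer_threshold_error", "error", "condition")))
  thr <- otsu_threshold(as.numeric(image))
  mask <- image > thr

  # fill holes below max_hole px: background components not touching border
  bg_lab <- EBImage::bwlabel((!mask) * 1L)
  if (max(bg_lab) > 0) {
    border <- unique(c(bg_lab[1, ], bg_lab[nrow(mask), ],
                       bg_lab[, 1], bg_lab[, ncol(mask)]))
    sizes <- tabulate(bg_lab[bg_lab > 0])
    fill <- setdiff(which(sizes < max_hole), border)
    if (length(fill)) mask[matrix(bg_lab %in% fill, nrow(mask))] <- TRUE
  }

  lab <- EBImage::bwlabel(mask * 1L)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_area)
    if (length(drop)) mask[matrix(lab %in% drop, nrow(mask))] <- FALSE
  }
  matrix(as.logical(mask), nrow(image), ncol(image))
}

# Local maxima of a distance map with a minimum separation, returned as a
# labelled seed image (plateaus collapse to one label).
distance_seeds <- function(dist, mask, min_sep) {
  dil <- gray_morph(dist, disc_brush(min_sep), "dilate")
  peaks <- (abs(dist - dil) < 1e-9) & mask & (dist >= 1)
  EBImage::bwlabel(peaks * 1L)
}

#' Split touching nuclei by seeded watershed
#'
#' Computes the Euclidean distance transform of the mask, seeds at its
#' local maxima (minimum separation = expected nuclear radius) and grows
#' the seeds through the mask; contested pixels go to the seed that is
#' closest in the geodesic sense, so touching nuclei split along the
#' equidistance line.
#'
#' @param mask logical matrix from [binarize_nuclei()].
#' @param min_sep minimum seed separation in px (expected nuclear radius).
#' @return integer label matrix (0 = background), compartment `nucleus`.
#' @export
split_nuclei <- function(mask, min_sep = 5) {
  storage.mode(mask) <- "integer"
  if (!any(mask == 1L))
    return(label_image(matrix(0L, nrow(mask), ncol(mask)), "nucleus"))
  dist <- EBImage::distmap(mask)
  seeds <- distance_seeds(as.matrix(dist), mask == 1L, min_sep)
  if (max(seeds) == 0) seeds[which.max(as.matrix(dist))] <- 1L
  # zero-gradient image makes the propagation metric purely spatial
  lab <- EBImage::propagate(matrix(0, nrow(mask), ncol(mask)), seeds,
                            mask = mask == 1L)
  label_image(relabel(matrix(as.integer(lab), nrow(mask), ncol(mask))),
              "nucleus")
}

label_image <- function(m, compartment) {
  storage.mode(m) <- "integer"
  attr(m, "compartment") <- compartment
  m
}

relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

#' Expand nuclei into cell and cytoplasm masks
#'
#' Centripetal expansion: all nuclei dilate outward together for
#' `n_pixels` rounds; contested pixels are assigned to the nearest nucleus,
#' so neighbouring cells halt at their equidistance boundary and labels
#' never overlap. The cytoplasm is the cell minus its nucleus. The
#' protocol convention is 3 px of expansion for 10X images and 6 px for
#' 40X; see [expansion_pixels()].
#'
#' @param nuclei integer nucleus label matrix from [split_nuclei()].
#' @param n_pixels expansion distance in px (>= 1).
#' @return list with `cell` and `cytoplasm` label matrices.
#' @export
expand_cytoplasm <- function(nuclei, n_pixels = 3L) {
  stopifnot(n_pixels >= 1)
  fg <- nuclei > 0
  if (!any(fg))
    return(list(cell = label_image(nuclei, "cell"),
                cytoplasm = label_image(nuclei, "cytoplasm")))
  bg <- matrix(1L, nrow(nuclei), ncol(nuclei)); bg[fg] <- 0L
  dist_to_fg <- as.matrix(EBImage::distmap(bg))
  cell_mask <- fg | (dist_to_fg <= n_pixels)
  cell <- EBImage::propagate(matrix(0, nrow(nuclei), ncol(nuclei)),
                             nuclei, mask = cell_mask)
  cell <- matrix(as.integer(cell), nrow(nuclei), ncol(nuclei))
  cyto <- cell; cyto[fg] <- 0L
  list(cell = label_image(cell, "cell"),
       cytoplasm = label_image(cyto, "cytoplasm"))
}

#' Cytoplasm expansion distance for a microscope objective
#'
#' @param objective `"10X"` or `"40X"`.
#' @return 3 px for 10X, 6 px for 40X.
#' @export
expansion_pixels <- function(objective = c("10X", "40X")) {
  switch(match.arg(objective), "10X" = 3L, "40X" = 6L)
}

#' Quantify per-cell intensities across all cycles and channels
#'
#' For every cell and every (cycle, channel) plane, computes the mean and
#' integrated (summed) intensity over the nucleus, cytoplasm and whole-cell
#' compartments, using only pixels valid in that cycle. Cells touching the
#' image border, or with more than half of their pixels invalid in any
#' cycle, are flagged `valid = FALSE` (kept, not dropped, so integrity
#' analyses retain full counts).
#'
#' @param labels list with `nucleus`, `cell`, `cytoplasm` label matrices
#'   sharing one label space.
#' @param stack a [assemble_stack()] result with matching (y, x) shape.
#' @return `CellTable` data.frame: `cell_id`, `centroid_x`, `centroid_y`
#'   (0-based px), `nucleus_area`, `cell_area` (px^2), `valid`, and one
#'   `cyc{c}_ch{k}_{nuc|cyto|cell}_{mean|int}` column per measurement.
#' @export
quantify <- function(labels, stack) {
  nuc <- labels$nucleus
  stopifnot(all(dim(nuc) == c(stack$dim[["height"]], stack$dim[["width"]])))
  n_cells <- max(0L, max(nuc), max(labels$cell))
  n_cyc <- stack$dim[["cycles"]]; n_chan <- stack$dim[["channels"]]
  H <- nrow(nuc); W <- ncol(nuc)

  comp_stats <- function(lab, plane, valid) {
    v <- as.numeric(plane); l <- as.integer(lab)
    keep <- l > 0L & valid & !is.na(v)
    s <- rowsum(v[keep], l[keep])
    cnt <- rowsum(rep(1, sum(keep)), l[keep])
    out_sum <- rep(NA_real_, n_cells); out_n <- rep(0, n_cells)
    ids <- as.integer(rownames(s))
    out_sum[ids] <- s[, 1]; out_n[ids] <- cnt[, 1]
    list(sum = out_sum, n = out_n)
  }

  base <- data.frame(cell_id = seq_len(n_cells))
  if (n_cells > 0) {
    idx <- which(nuc > 0)
    ys <- (idx - 1) %% H; xs <- (idx - 1) %/% H
    l <- nuc[idx]
    base$centroid_x <- as.numeric(rowsum(xs, l)[, 1] / tabulate(l, n_cells))
    base$centroid_y <- as.numeric(rowsum(ys, l)[, 1] / tabulate(l, n_cells))
    base$nucleus_area <- tabulate(nuc[nuc > 0], n_cells)
    base$cell_area <- tabulate(labels$cell[labels$cell > 0], n_cells)
  } else {
    base$centroid_x <- base$centroid_y <- numeric(0)
    base$nucleus_area <- base$cell_area <- integer(0)
  }

  border_labels <- unique(c(labels$cell[1, ], labels$cell[H, ],
                            labels$cell[, 1], labels$cell[, W]))
  valid_flag <- rep(TRUE, n_cells)
  valid_flag[border_labels[border_labels > 0]] <- FALSE

  cols <- list()
  comp_names <- c(nuc = "nucleus", cyto = "cytoplasm", cell = "cell")
  cell_px <- if (n_cells) tabulate(labels$cell[labels$cell > 0], n_cells) else integer(0)
  for (cc in seq_len(n_cyc)) {
    vmask <- as.logical(stack$valid[cc, , ])
    if (n_cells) {
      st_cell_valid <- comp_stats(labels$cell, matrix(1, H, W), vmask)
      frac_invalid <- 1 - st_cell_valid$n / pmax(cell_px, 1)
      valid_flag[frac_invalid > 0.5] <- FALSE
    }
    for (k in seq_len(n_chan) - 1L) {
      plane <- matrix(stack$data[cc, k + 1L, , ], H, W)
      for (cn in names(comp_names)) {
        lab <- labels[[comp_names[[cn]]]]
        st <- comp_stats(lab, plane, vmask)
        mean_v <- ifelse(st$n > 0, st$sum / st$n, NA_real_)
        int_v <- ifelse(st$n > 0, st$sum, NA_real_)
        cols[[sprintf("cyc%d_ch%d_%s_mean", cc, k, cn)]] <- mean_v
        cols[[sprintf("cyc%d_ch%d_%s_int", cc, k, cn)]] <- int_v
      }
    }
  }
  ct <- cbind(base,
              field_id = rep(NA_character_, n_cells),
              region_label = rep(NA_character_, n_cells),
              valid = valid_flag,
              as.data.frame(cols))
  ct <- ct[order(ct$cell_id), , drop = FALSE]
  rownames(ct) <- NULL
  class(ct) <- c("CellTable", "data.frame")
  ct
}

#' Map marker names to (cycle, channel) measurement columns
#'
#' With the four-channel convention (channel 0 nuclear), marker `m` of the
#' panel appears in cycle `(m - 1) %/% 3 + 1`, channel `(m - 1) %% 3 + 1`.
#'
#' @param markers character vector of marker names in acquisition order.
#' @param channels_per_cycle channels per cycle including the nuclear one.
#' @return data.frame marker/cycle/channel.
#' @export
marker_channel_map <- function(markers, channels_per_cycle = 4L) {
  nmc <- channels_per_cycle - 1L
  data.frame(marker = markers,
             cycle = (seq_along(markers) - 1L) %/% nmc + 1L,
             channel = (seq_along(markers) - 1L) %% nmc + 1L,
             stringsAsFactors = FALSE)
}

#' Extract a cells x markers intensity matrix from a CellTable
#'
#' @param celltable a [quantify()] result.
#' @param map a [marker_channel_map()].
#' @param compartment `"cell"`, `"nuc"` or `"cyto"`.
#' @param statistic `"mean"` or `"int"`.
#' @export
marker_matrix <- function(celltable, map, compartment = "cell",
                          statistic = "mean") {
  cols <- sprintf("cyc%d_ch%d_%s_%s", map$cycle, map$channel,
                  compartment, statistic)
  missing <- setdiff(cols, names(celltable))
  if (length(missing)) stop("columns absent from cell table: ",
                            paste(missing, collapse = ", "))
  m <- as.matrix(celltable[, cols, drop = FALSE])
  colnames(m) <- map$marker
  m
}
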