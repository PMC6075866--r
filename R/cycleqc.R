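# Cycle-level quality control: fluorophore-inactivation folds, tissue
# integrity across cycles, dynamic range, distribution overlap and nominal
# optical resolution.

#' Fluorophore inactivation fold
#'
#' Fold reduction in background-corrected median cell intensity after a
#' bleaching round. Medians are used so segmentation outliers do not
#' dominate. Effective inactivation reduces signal by two to three orders
#' of magnitude.
#'
#' @param pre,post per-cell mean intensities of the same segmented cells
#'   before and after inactivation.
#' @param background scalar background intensity level.
#' @return fold = (median(pre) - background) / max(median(post) - background, eps).
#' @export
inactivation_fold <- function(pre, post, background = 0) {
  if (!length(pre) || !length(post)) stop("empty cell set")
  num <- stats::median(pre) - background
  den <- max(stats::median(post) - background, .Machine$double.eps)
  max(num, 0) / den
}

#' Match nuclei between two cycles and compute the retained fraction
#'
#' Greedy mutual-nearest-neighbour matching of registered centroids: a pair
#' is matched when each is the other's nearest neighbour and they lie
#' within `max_dist`; pairs are accepted in order of increasing distance.
#'
#' @param table_a,table_b CellTables (or data.frames with `centroid_x`,
#'   `centroid_y`) in the same registered coordinates.
#' @param max_dist matching radius in px (default: the median nuclear
#'   radius implied by `nucleus_area` of `table_a`).
#' @return list with `matches` (data.frame id_a, id_b, dist) and
#'   `retained` = |matched| / |table_a|.
#' @export
match_nuclei <- function(table_a, table_b, max_dist = NULL) {
  if (is.null(max_dist))
    max_dist <- stats::median(sqrt(table_a$nucleus_area / pi))
  na <- nrow(table_a); nb <- nrow(table_b)
  if (na == 0 || nb == 0)
    return(list(matches = data.frame(id_a = integer(0), id_b = integer(0),
                                     dist = numeric(0)),
                retained = if (na == 0) NA_real_ else 0))
  d2 <- outer(table_a$centroid_x, table_b$centroid_x, "-")^2 +
        outer(table_a$centroid_y, table_b$centroid_y, "-")^2
  nn_ab <- apply(d2, 1, which.min)          # nearest b for each a
  nn_ba <- apply(d2, 2, which.min)          # nearest a for each b
  mutual <- which(nn_ba[nn_ab] == seq_len(na))
  dist <- sqrt(d2[cbind(mutual, nn_ab[mutual])])
  keep <- dist <= max_dist
  ord <- order(dist[keep])
  matches <- data.frame(id_a = table_a$cell_id[mutual[keep]][ord],
                        id_b = table_b$cell_id[nn_ab[mutual[keep]]][ord],
                        dist = dist[keep][ord])
  list(matches = matches, retained = nrow(matches) / na)
}

#' Tissue-integrity curve across cycles
#'
#' Nucleus counts per cycle normalized to the first cycle. Values slightly
#' above 1 can occur through segmentation fluctuations.
#'
#' @param counts integer vector of nucleus counts for cycles 1..N, or a
#'   list of CellTables whose rows are counted.
#' @return numeric vector of ratios, first element 1.
#' @export
integrity_curve <- function(counts) {
  if (is.list(counts) && !is.numeric(counts))
    counts <- vapply(counts, nrow, integer(1))
  stopifnot(length(counts) >= 2, counts[1] > 0)
  counts / counts[1]
}

#' Dynamic range of an intensity sample
#'
#' `log10(P95 / P5)` of the values, with percentiles by linear
#' interpolation; intensities below the 5th percentile are regarded as
#' background, so the ratio approximates the signal-to-noise ratio. A
#' shrinking background raises the dynamic range even at fixed signal,
#' which is why the measure often improves with cycle number as
#' autofluorescence is bleached away.
#'
#' @param values >= 20 positive intensities.
#' @return dynamic range in log10 units.
#' @export
dynamic_range <- function(values) {
  stopifnot(length(values) >= 20)
  q <- stats::quantile(values, c(0.05, 0.95), names = FALSE, type = 7)
  if (q[1] <= 0)
    stop("5th percentile is not positive; offset the background before computing dynamic range")
  log10(q[2] / q[1])
}

#' Overlap score between two intensity distributions
#'
#' Both samples are histogram-estimated as unit-area densities on a shared
#' support (the union of each sample's 0.1-99.9 percentile range); the
#' score is the trapezoidal integral of the pointwise minimum envelope over
#' the integral of the pointwise maximum envelope. 1 means identical
#' distributions, 0 disjoint ones.
#'
#' @param values_a,values_b non-empty numeric samples.
#' @param n_bins number of shared histogram bins (default 100).
#' @return score in `[0, 1]`.
#' @export
overlap_score <- function(values_a, values_b, n_bins = 100L) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  ra <- stats::quantile(values_a, c(0.001, 0.999), names = FALSE)
  rb <- stats::quantile(values_b, c(0.001, 0.999), names = FALSE)
  lo <- min(ra[1], rb[1]); hi <- max(ra[2], rb[2])
  if (hi == lo) return(1)   # all values identical in both samples
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  dens <- function(v) {
    v <- v[v >= lo & v <= hi]
    h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
    d <- h / (length(v) * diff(breaks))
    area <- trapz(mids, d)
    if (area > 0) d / area else d
  }
  da <- dens(values_a); db <- dens(values_b)
  total <- trapz(mids, pmax(da, db))
  if (total == 0) return(1)
  trapz(mids, pmin(da, db)) / total
}

#' Concordance class of an overlap score
#'
#' Thresholds follow the three-colour convention for between-slide staining
#' concordance: scores above 0.8 are high, below 0.6 low, and the closed
#' interval `[0.6, 0.8]` moderate.
#'
#' @param score overlap score(s) in `[0, 1]`.
#' @return character vector: `"high"`, `"moderate"` or `"low"`.
#' @export
classify_concordance <- function(score) {
  stopifnot(all(score >= 0 & score <= 1))
  ifelse(score > 0.8, "high", ifelse(score >= 0.6, "moderate", "low"))
}

#' Nominal optical resolution of a microscope objective
#'
#' Rayleigh-type criterion: `0.61 * lambda / NA` for widefield and
#' `0.4 * lambda / NA` for confocal microscopy.
#'
#' @param wavelength_nm emission wavelength in nm (default 520).
#' @param numerical_aperture objective NA in (0, 1.7].
#' @param mode `"widefield"` or `"confocal"`.
#' @return nominal resolution in um.
#' @export
nominal_resolution <- function(wavelength_nm = 520, numerical_aperture,
                               mode = c("widefield", "confocal")) {
  mode <- match.arg(mode)
  stopifnot(wavelength_nm > 0,
            numerical_aperture > 0, numerical_aperture <= 1.7)
  coef <- if (mode == "widefield") 0.61 else 0.4
  coef * wavelength_nm / numerical_aperture / 1000
}

#' Assemble a per-run QC report
#'
#' @param integrity integrity-curve vector (cycle 1 first).
#' @param dynamic_ranges named list or data.frame of per (cycle, channel)
#'   dynamic ranges.
#' @param overlaps optional data.frame with an added `class` column from
#'   [classify_concordance()].
#' @param inactivation optional named vector of inactivation folds.
#' @param parameters parameters used.
#' @return list of class `QCReport`.
#' @export
qc_report <- function(integrity, dynamic_ranges = NULL, overlaps = NULL,
                      inactivation = NULL, parameters = list()) {
  stopifnot(abs(integrity[1] - 1) < 1e-12)
  structure(list(integrity = integrity, dynamic_ranges = dynamic_ranges,
                 overlaps = overlaps, inactivation = inactivation,
                 parameters = parameters),
            class = "QCReport")
}
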