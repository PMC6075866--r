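#' Acquisition model for synthetic multi-cycle imaging
#'
#' Describes how the ideal tissue scene is turned into raw image tiles:
#' the tile grid and overlap, per-cycle rigid stage drift, a smooth
#' multiplicative illumination-shading field (identical for every tile, as
#' for a fixed optical train), an additive autofluorescence background that
#' decays with cycle number (bleaching rounds progressively destroy the
#' endogenous background), and a Poisson + Gaussian-read camera noise model.
#'
#' @param ... named overrides of the defaults. Key fields: `grid` (rows,
#'   cols), `tile` (width, height px), `overlap` fraction in (0, 0.5),
#'   `n_cycles`, `channels_per_cycle` (channel 0 is the nuclear stain),
#'   `offsets` (n_cycles x 3 matrix: dx, dy px and theta radians; row 1 must
#'   be zero), `shading` (`amplitude` of the radial vignette), `af`
#'   (`amplitude` at cycle 1 and per-cycle `decay` in (0, 1]), `noise`
#'   (`photons_per_count` for Poisson shot noise, 0 disables; `read_sd`),
#'   `nuclear_amp` (peak nuclear-stain intensity).
#' @return a validated list of class `AcquisitionModel`.
#' @export
acquisition_model <- function(...) {
  defaults <- list(
    grid = c(rows = 2L, cols = 2L),
    tile = c(width = 256L, height = 256L),
    overlap = 0.125,
    n_cycles = 3L,
    channels_per_cycle = 4L,
    offsets = rbind(c(0, 0, 0),
                    c(4, -3, 0.1 * pi / 180),
                    c(-2.5, 1.5, -0.15 * pi / 180)),
    shading = list(amplitude = 0.2),
    af = list(amplitude = 150, decay = 0.6),
    noise = list(photons_per_count = 0.25, read_sd = 2),
    nuclear_amp = 2000
  )
  acq <- merge_config(defaults, list(...))
  if (is.null(dim(acq$offsets))) acq$offsets <- matrix(acq$offsets, ncol = 3)
  if (nrow(acq$offsets) < acq$n_cycles)
    stop("offsets must have one row per cycle")
  acq$offsets <- acq$offsets[seq_len(acq$n_cycles), , drop = FALSE]
  colnames(acq$offsets) <- c("dx", "dy", "theta")
  if (any(acq$offsets[1, ] != 0))
    stop("cycle 1 is the reference: its offset must be (0, 0, 0)")
  if (acq$overlap <= 0 || acq$overlap >= 0.5)
    stop("overlap fraction must lie in (0, 0.5)")
  if (acq$af$decay <= 0 || acq$af$decay > 1)
    stop("autofluorescence decay must lie in (0, 1] (non-increasing background)")
  if (acq$shading$amplitude < 0 || acq$shading$amplitude >= 1)
    stop("shading amplitude must lie in [0, 1) to keep the field positive")
  class(acq) <- "AcquisitionModel"
  acq
}

#' Illumination shading field of an acquisition model
#'
#' Radial vignette over one tile, renormalized to mean exactly 1 and
#' strictly positive.
#' @param acq an [acquisition_model()].
#' @return tile-shaped matrix.
#' @export
shading_field <- function(acq) {
  w <- acq$tile[["width"]]; h <- acq$tile[["height"]]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  r2 <- outer((0:(h - 1) - cy)^2, (0:(w - 1) - cx)^2, "+")
  s <- 1 - acq$shading$amplitude * r2 / max(r2)
  s / mean(s)
}

#' Per-cycle autofluorescence amplitudes (non-increasing)
#' @param acq an [acquisition_model()].
#' @export
af_schedule <- function(acq)
  acq$af$amplitude * acq$af$decay^(seq_len(acq$n_cycles) - 1)

#' Tile origins and mosaic extent implied by an acquisition model
#' @param acq an [acquisition_model()].
#' @return list with `origins` (row/col/ox/oy data.frame), `stride`, and
#'   the stitched `mosaic` size.
#' @export
tile_layout <- function(acq) {
  w <- acq$tile[["width"]]; h <- acq$tile[["height"]]
  sx <- round(w * (1 - acq$overlap)); sy <- round(h * (1 - acq$overlap))
  rows <- acq$grid[["rows"]]; cols <- acq$grid[["cols"]]
  g <- expand.grid(row = 0:(rows - 1), col = 0:(cols - 1))
  g$ox <- g$col * sx; g$oy <- g$row * sy
  list(origins = g, stride = c(x = sx, y = sy),
       mosaic = c(width = w + (cols - 1) * sx, height = h + (rows - 1) * sy))
}

#' Render soft-edged cell profiles onto a blank canvas
#'
#' Each cell is a flat-core disk (core radius `max(r - edge_sigma, r/2)`)
#' with a Gaussian edge skirt of width `edge_sigma`, truncated at 3 edge
#' sigmas; the half-maximum of the profile falls at approximately the true
#' radius, so intensity thresholding recovers the nominal disk area.
#'
#' @param w,h canvas size in px.
#' @param xs,ys cell centers (0-based px).
#' @param radii nuclear radii in px.
#' @param amps peak amplitudes.
#' @param edge_sigma edge softness in px.
#' @return h x w matrix with profiles summed additively.
#' @export
render_spots <- function(w, h, xs, ys, radii, amps, edge_sigma = 0.75) {
  img <- matrix(0, h, w)
  for (i in seq_along(xs)) {
    core <- max(radii[i] - edge_sigma, radii[i] / 2)
    rad <- ceiling(core + 3 * edge_sigma)
    x0 <- max(0, floor(xs[i]) - rad); x1 <- min(w - 1, ceiling(xs[i]) + rad)
    y0 <- max(0, floor(ys[i]) - rad); y1 <- min(h - 1, ceiling(ys[i]) + rad)
    if (x0 > x1 || y0 > y1) next
    dx2 <- (x0:x1 - xs[i])^2; dy2 <- (y0:y1 - ys[i])^2
    d <- sqrt(outer(dy2, dx2, "+"))
    g <- amps[i] * exp(-pmax(d - core, 0)^2 / (2 * edge_sigma^2))
    g[d > core + 3 * edge_sigma] <- 0
    img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <-
      img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] + g
  }
  img
}

#' Render a phantom into raw multi-cycle image tiles
#'
#' For every cycle, cells that have detached (`dropout_cycle <= cycle`) are
#' omitted, the surviving cells are moved by the cycle's rigid stage offset
#' (rotation about the mosaic center, then translation), and each channel is
#' rendered as soft-edged disks (flat core, Gaussian skirt, half-maximum at
#' the true nuclear radius): the nuclear channel at a fixed peak
#' amplitude, marker channels scaled by each cell's true expression. The
#' ideal scene is then cut into overlapping tiles; each tile receives the
#' cycle's additive autofluorescence, is multiplied by the shading field,
#' and is degraded by Poisson shot noise and Gaussian read noise before
#' quantization to 16-bit counts.
#'
#' @param phantom a [generate_phantom()] result.
#' @param acq an [acquisition_model()].
#' @param seed integer seed for the noise draws.
#' @param expression_scale scalar multiplier on marker amplitudes (used to
#'   emulate residual signal after fluorophore inactivation).
#' @return an object of class `RawTileSet`: `tiles` (named list of integer
#'   matrices, names `cyc{cc}_ch{k}_r{row}_c{col}`), `index` (data.frame),
#'   `ideal` (per cycle per channel noise-free mosaics), and `manifest`
#'   (applied transforms, autofluorescence schedule, shading field, layout).
#' @export
render_cycles <- function(phantom, acq, seed = 1L, expression_scale = 1) {
  stopifnot(inherits(phantom, "TissuePhantom"), inherits(acq, "AcquisitionModel"))
  lay <- tile_layout(acq)
  W <- lay$mosaic[["width"]]; H <- lay$mosaic[["height"]]
  if (phantom$canvas[["width"]] > W || phantom$canvas[["height"]] > H)
    stop(errorCondition(
      sprintf("tile grid (%dx%d px mosaic) does not cover the %dx%d px phantom canvas",
              W, H, phantom$canvas[["width"]], phantom$canvas[["height"]]),
      class = c("cycifer_config_error", "error", "condition")))
  n_mark_chan <- acq$channels_per_cycle - 1L
  need <- acq$n_cycles * n_mark_chan
  if (ncol(phantom$expression) < need && nrow(phantom$cells) > 0)
    stop(sprintf("phantom carries %d markers but %d cycles x %d marker channels need %d",
                 ncol(phantom$expression), acq$n_cycles, n_mark_chan, need))
  af <- af_schedule(acq)
  sh <- shading_field(acq)
  cells <- phantom$cells
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  tw <- acq$tile[["width"]]; th <- acq$tile[["height"]]
  pp <- acq$noise$photons_per_count; rsd <- acq$noise$read_sd

  tiles <- list(); idx <- list(); ideal <- vector("list", acq$n_cycles)
  with_seed(seed, {
    for (cc in seq_len(acq$n_cycles)) {
      alive <- which(is.na(cells$dropout_cycle) | cells$dropout_cycle > cc)
      th_c <- acq$offsets[cc, "theta"]
      xs <- cos(th_c) * (cells$x[alive] - cx) - sin(th_c) * (cells$y[alive] - cy) +
            cx + acq$offsets[cc, "dx"]
      ys <- sin(th_c) * (cells$x[alive] - cx) + cos(th_c) * (cells$y[alive] - cy) +
            cy + acq$offsets[cc, "dy"]
      rad <- cells$radius[alive]
      ideal[[cc]] <- vector("list", acq$channels_per_cycle)
      for (k in 0:(acq$channels_per_cycle - 1L)) {
        amps <- if (k == 0) rep(acq$nuclear_amp, length(alive))
                else expression_scale *
                     phantom$expression[alive, (cc - 1L) * n_mark_chan + k]
        plane <- render_spots(W, H, xs, ys, rad, amps)
        ideal[[cc]][[k + 1L]] <- plane
        for (t in seq_len(nrow(lay$origins))) {
          ox <- lay$origins$ox[t]; oy <- lay$origins$oy[t]
          sub <- plane[(oy + 1):(oy + th), (ox + 1):(ox + tw)]
          img <- (sub + af[cc]) * sh
          if (pp > 0) img <- stats::rpois(length(img), img * pp) / pp
          if (rsd > 0) img <- img + stats::rnorm(length(img), 0, rsd)
          img <- matrix(pmin(pmax(round(img), 0), 65535), th, tw)
          storage.mode(img) <- "integer"
          nm <- sprintf("cyc%02d_ch%d_r%d_c%d", cc, k,
                        lay$origins$row[t], lay$origins$col[t])
          tiles[[nm]] <- img
          idx[[length(idx) + 1L]] <- data.frame(
            name = nm, cycle = cc, channel = k,
            row = lay$origins$row[t], col = lay$origins$col[t],
            ox = ox, oy = oy, stringsAsFactors = FALSE)
        }
      }
    }
  })
  transforms <- data.frame(cycle = seq_len(acq$n_cycles),
                           dx = acq$offsets[, "dx"], dy = acq$offsets[, "dy"],
                           theta = acq$offsets[, "theta"])
  structure(list(
    tiles = tiles, index = do.call(rbind, idx), ideal = ideal,
    manifest = list(transforms = transforms, autofluorescence = af,
                    shading = sh, layout = lay, acq = acq,
                    expression_scale = expression_scale, seed = seed)),
    class = "RawTileSet")
}

#' @export
print.RawTileSet <- function(x, ...) {
  cat(sprintf("RawTileSet: %d tiles (%d cycles x %d channels x %d grid positions)\n",
              length(x$tiles), max(x$index$cycle), max(x$index$channel) + 1L,
              nrow(x$manifest$layout$origins)))
  invisible(x)
}
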