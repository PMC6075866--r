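# Tile correction, stitching and cross-cycle rigid registration.
#
# The nuclear (DNA) channel is imaged every cycle and serves as the
# registration reference; marker channels of a cycle inherit that cycle's
# rigid transform.

#' Rigid transform (translation + small rotation)
#'
#' @param dx,dy translation in px (sub-pixel allowed).
#' @param theta rotation in radians about the image center.
#' @param reference index of the reference cycle (identity transform).
#' @return list of class `RigidTransform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, theta = 0, reference = 1L) {
  structure(list(dx = dx, dy = dy, theta = theta, reference = reference),
            class = "RigidTransform")
}

#' Apply a rigid transform to 0-based point coordinates
#' @param tr a [rigid_transform()].
#' @param xy n x 2 matrix of (x, y).
#' @param center rotation center (x, y); typically `(dim - 1) / 2`.
#' @export
apply_transform <- function(tr, xy, center) {
  xy <- rbind(xy)
  x <- xy[, 1] - center[1]; y <- xy[, 2] - center[2]
  cbind(cos(tr$theta) * x - sin(tr$theta) * y + center[1] + tr$dx,
        sin(tr$theta) * x + cos(tr$theta) * y + center[2] + tr$dy)
}

#' @rdname rigid_transform
#' @param tr transform to invert.
#' @export
invert_transform <- function(tr) {
  ct <- cos(-tr$theta); st <- sin(-tr$theta)
  rigid_transform(dx = -(ct * tr$dx - st * tr$dy),
                  dy = -(st * tr$dx + ct * tr$dy),
                  theta = -tr$theta, reference = tr$reference)
}

#' @rdname rigid_transform
#' @param t1,t2 transforms; the composition applies `t2` then `t1`.
#' @export
compose_transform <- function(t1, t2) {
  ct <- cos(t1$theta); st <- sin(t1$theta)
  rigid_transform(dx = ct * t2$dx - st * t2$dy + t1$dx,
                  dy = st * t2$dx + ct * t2$dy + t1$dy,
                  theta = t1$theta + t2$theta, reference = t1$reference)
}

# Hann-windowed, mean-removed cross-correlation via FFT. Returns the
# translation t (dy, dx, sub-pixel) such that `b` equals `a` shifted by t,
# plus the Cauchy-Schwarz-normalized correlation peak as a confidence
# score in [0, 1]. Plain (unwhitened) correlation is used because its peak
# localizes far more precisely than phase correlation on narrow,
# noise-dominated overlap strips.
phase_correlate <- function(a, b, window = TRUE) {
  stopifnot(all(dim(a) == dim(b)))
  h <- nrow(a); w <- ncol(a)
  if (window) {
    wy <- 0.5 - 0.5 * cos(2 * pi * (0:(h - 1)) / (h - 1))
    wx <- 0.5 - 0.5 * cos(2 * pi * (0:(w - 1)) / (w - 1))
    wm <- outer(wy, wx)
    a <- (a - mean(a)) * wm; b <- (b - mean(b)) * wm
  }
  A <- stats::fft(a); B <- stats::fft(b)
  R <- A * Conj(B)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  k <- which.max(r)
  iy <- (k - 1) %% h; ix <- (k - 1) %/% h
  wrap <- function(i, n) if (i > n / 2) i - n else i
  py <- wrap(iy, h); px <- wrap(ix, w)
  # refine around the integer peak by evaluating the inverse DFT of the
  # cross-power spectrum on an upsampled local grid (50x)
  fy <- 0:(h - 1); fy[fy > h / 2] <- fy[fy > h / 2] - h
  fx <- 0:(w - 1); fx[fx > w / 2] <- fx[fx > w / 2] - w
  uy <- py + seq(-1, 1, by = 0.02); ux <- px + seq(-1, 1, by = 0.02)
  Ky <- exp(2i * pi * outer(uy, fy) / h)
  Kx <- exp(2i * pi * outer(ux, fx) / w)
  rup <- Re(Ky %*% R %*% t(Kx)) / length(R)
  kk <- which.max(rup)
  dy <- uy[(kk - 1) %% length(uy) + 1]
  dx <- ux[(kk - 1) %/% length(uy) + 1]
  # peak at lag i means b(q) = a(q - i): negate to report the shift a -> b
  conf <- r[k] / max(sqrt(sum(a^2)) * sqrt(sum(b^2)), .Machine$double.eps)
  list(dy = -dy, dx = -dx, peak = conf)
}

# Bilinear rotation of an image by theta about its center (out-of-frame
# pixels fill with `fill`).
rotate_image <- function(img, theta, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  g <- expand.grid(y = 0:(h - 1), x = 0:(w - 1))
  xs <- cos(theta) * (g$x - cx) - sin(theta) * (g$y - cy) + cx
  ys <- sin(theta) * (g$x - cx) + cos(theta) * (g$y - cy) + cy
  v <- bilinear_sample(img, xs, ys)
  v[is.na(v)] <- fill
  matrix(v, h, w)
}

#' Estimate an illumination-shading model from same-channel tiles
#'
#' Retrospective estimator: the per-pixel median across many tiles isolates
#' the smooth multiplicative illumination field (sparse bright cells are
#' rejected by the median), which is then Gaussian-smoothed and renormalized
#' to mean 1. An optional additive darkfield is the per-pixel 1st
#' percentile.
#'
#' @param tiles list of >= 8 same-shape matrices from one channel.
#' @param smooth_sigma Gaussian smoothing sigma in px (default tile width / 16).
#' @param darkfield estimate an additive darkfield image as well?
#' @return list of class `ShadingModel` with `flatfield` (mean 1,
#'   multiplicative) and `darkfield` (additive).
#' @export
estimate_shading <- function(tiles, smooth_sigma = NULL, darkfield = FALSE) {
  if (length(tiles) < 8L)
    stop("estimate_shading needs >= 8 tiles (got ", length(tiles),
         "); the median-based estimator is unreliable below that")
  dm <- dim(tiles[[1]])
  stopifnot(all(vapply(tiles, function(t) all(dim(t) == dm), TRUE)))
  mat <- vapply(tiles, as.numeric, numeric(prod(dm)))
  med <- matrix(apply(mat, 1, stats::median), dm[1], dm[2])
  if (is.null(smooth_sigma)) smooth_sigma <- dm[2] / 16
  sm <- as.matrix(EBImage::gblur(med, sigma = smooth_sigma,
                                 boundary = "replicate"))
  if (mean(sm) <= 0) stop("degenerate tiles: non-positive median field")
  flat <- sm / mean(sm)
  flat[flat <= 0] <- min(flat[flat > 0])
  dark <- if (darkfield)
    matrix(apply(mat, 1, stats::quantile, probs = 0.01, names = FALSE),
           dm[1], dm[2])
  else matrix(0, dm[1], dm[2])
  structure(list(flatfield = flat / mean(flat), darkfield = dark),
            class = "ShadingModel")
}

#' Apply a shading model to a tile
#' @param tile image matrix.
#' @param shading a [estimate_shading()] result.
#' @return corrected image `(tile - darkfield) / flatfield`, clipped at 0.
#' @export
correct_tile <- function(tile, shading) {
  if (!all(dim(tile) == dim(shading$flatfield)))
    stop("tile and shading model shapes differ")
  clip0((tile - shading$darkfield) / shading$flatfield)
}

#' Rolling-ball background subtraction
#'
#' Removes slowly varying background by grayscale opening with a disc
#' structuring element of the given radius; features smaller than the ball
#' are preserved.
#'
#' @param image matrix.
#' @param radius structuring-element radius in px (default 50).
#' @return background-subtracted image (>= 0).
#' @export
subtract_background <- function(image, radius = 50) {
  stopifnot(radius >= 1)
  if (2 * radius + 1 > min(dim(image)))
    stop("rolling-ball radius ", radius, " too large for a ",
         paste(dim(image), collapse = "x"), " image")
  br <- disc_brush(radius)
  bg <- gray_morph(gray_morph(image, br, "erode"), br, "dilate")
  clip0(image - bg)
}

#' Unsharp masking
#'
#' @param image matrix.
#' @param radius Gaussian blur sigma in px.
#' @param amount high-frequency weight in `[0, 1]`.
#' @return sharpened image `image + amount * (image - blur)`, clipped at 0.
#' @export
unsharp_mask <- function(image, radius = 2, amount = 0.5) {
  stopifnot(amount >= 0, amount <= 1)
  if (amount == 0) return(image)
  blur <- as.matrix(EBImage::gblur(image, sigma = radius))
  clip0(image + amount * (image - blur))
}

#' Stitch a tile grid into a mosaic
#'
#' Pairwise offsets between grid neighbours are estimated by phase
#' correlation within the nominal overlap strips, reconciled globally by
#' least squares over the tile graph (anchored on the first tile), and the
#' tiles are composited with linear feathering in the overlap zones. Pairs
#' whose correlation peak falls below `min_confidence` fall back to the
#' nominal offset and are recorded as warnings.
#'
#' @param tiles named list of same-shape matrices.
#' @param index data.frame with columns `row`, `col`, `ox`, `oy` (nominal
#'   0-based origins), rows aligned with `tiles`.
#' @param stride nominal grid stride `c(x = , y = )`; the nominal overlap is
#'   `tile - stride` and must be >= 20 px (unless there is a single tile).
#' @param min_confidence phase-correlation peak below which a pair is
#'   considered featureless.
#' @return list with `mosaic`, `offsets` (per-tile refined sub-pixel
#'   origins + confidence) and `warnings`.
#' @export
stitch_grid <- function(tiles, index, stride, min_confidence = 0.2) {
  n <- length(tiles)
  stopifnot(n == nrow(index))
  th <- nrow(tiles[[1]]); tw <- ncol(tiles[[1]])
  if (n == 1L)
    return(list(mosaic = tiles[[1]],
                offsets = cbind(index, ox_refined = index$ox,
                                oy_refined = index$oy, confidence = NA_real_),
                warnings = character(0)))
  ovx <- tw - stride[["x"]]; ovy <- th - stride[["y"]]
  if (ovx < 20 || ovy < 20)
    stop("declared tile overlap must be >= 20 px (got ", ovx, "x", ovy, ")")

  warnings <- character(0)
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      right <- index$row[j] == index$row[i] & index$col[j] == index$col[i] + 1L
      down  <- index$col[j] == index$col[i] & index$row[j] == index$row[i] + 1L
      if (!right && !down) next
      if (right) {
        sa <- tiles[[i]][, (tw - ovx + 1):tw, drop = FALSE]
        sb <- tiles[[j]][, 1:ovx, drop = FALSE]
        nominal <- c(x = stride[["x"]], y = 0)
      } else {
        sa <- tiles[[i]][(th - ovy + 1):th, , drop = FALSE]
        sb <- tiles[[j]][1:ovy, , drop = FALSE]
        nominal <- c(x = 0, y = stride[["y"]])
      }
      pc <- phase_correlate(sa, sb)
      if (pc$peak < min_confidence) {
        warnings <- c(warnings, sprintf(
          "featureless overlap between tile (%d,%d) and (%d,%d): using nominal offset",
          index$row[i], index$col[i], index$row[j], index$col[j]))
        d <- nominal
      } else {
        # strip B equals strip A shifted by (pc$dy, pc$dx) => the actual
        # displacement deviates from nominal by the opposite sign
        d <- c(x = nominal[["x"]] - pc$dx, y = nominal[["y"]] - pc$dy)
      }
      edges[[length(edges) + 1L]] <- list(i = i, j = j, d = d, peak = pc$peak)
    }
  }

  # least-squares reconciliation, anchored on tile 1 at its nominal origin
  solve_axis <- function(axis, anchor) {
    A <- matrix(0, length(edges), n); rhs <- numeric(length(edges))
    for (e in seq_along(edges)) {
      A[e, edges[[e]]$i] <- -1; A[e, edges[[e]]$j] <- 1
      rhs[e] <- edges[[e]]$d[[axis]]
    }
    rhs <- rhs - A[, 1] * anchor
    sol <- qr.solve(A[, -1, drop = FALSE], rhs)
    c(anchor, sol + 0)  # tile 1 fixed
  }
  ox <- solve_axis("x", index$ox[1])
  oy <- solve_axis("y", index$oy[1])

  # composite on a canvas padded for refined origins that stray outside the
  # nominal frame, then crop back to the nominal mosaic extent (a residual
  # whole-frame shift is absorbed later by cycle registration)
  oxi <- round(ox); oyi <- round(oy)
  Wn <- max(index$ox) + tw; Hn <- max(index$oy) + th
  padx <- -min(0, min(oxi)); pady <- -min(0, min(oyi))
  W <- max(Wn, max(oxi) + tw) + padx; H <- max(Hn, max(oyi) + th) + pady
  S <- matrix(0, H, W); Wt <- matrix(0, H, W)
  wx <- pmin(1, ((1:tw) - 0.5) / ovx, (tw - (1:tw) + 0.5) / ovx)
  wy <- pmin(1, ((1:th) - 0.5) / ovy, (th - (1:th) + 0.5) / ovy)
  wmat <- outer(wy, wx)
  for (i in seq_len(n)) {
    ry <- (pady + oyi[i] + 1):(pady + oyi[i] + th)
    rx <- (padx + oxi[i] + 1):(padx + oxi[i] + tw)
    S[ry, rx] <- S[ry, rx] + tiles[[i]] * wmat
    Wt[ry, rx] <- Wt[ry, rx] + wmat
  }
  mosaic <- ifelse(Wt > 0, S / pmax(Wt, .Machine$double.eps), 0)
  mosaic <- mosaic[(pady + 1):(pady + Hn), (padx + 1):(padx + Wn)]

  conf <- vapply(seq_len(n), function(i) {
    pk <- unlist(lapply(edges, function(e)
      if (e$i == i || e$j == i) e$peak else NULL))
    if (length(pk)) min(pk) else NA_real_
  }, numeric(1))
  list(mosaic = mosaic,
       offsets = cbind(index, ox_refined = ox, oy_refined = oy,
                       confidence = conf),
       warnings = warnings)
}

#' Register per-cycle nuclear mosaics to a reference cycle
#'
#' Translation is recovered by Hann-windowed phase correlation with
#' parabolic sub-pixel peak interpolation. Rotation is recovered by a 1-D
#' search: candidate angles on a fixed grid are scored by the
#' phase-correlation peak after de-rotating the moving mosaic, and the best
#' candidate is refined by golden-section search.
#'
#' @param mosaics list of same-shape nuclear-channel mosaics, one per cycle.
#' @param reference reference cycle index (its transform is the identity).
#' @param max_theta half-width of the rotation search in radians (default
#'   2 degrees; 0 disables the rotation search).
#' @param theta_step grid step of the coarse search (default 0.05 degrees).
#' @param min_confidence minimum acceptable correlation peak.
#' @return list of [rigid_transform()]s mapping reference coordinates into
#'   each cycle's mosaic.
#' @export
register_cycles <- function(mosaics, reference = 1L,
                            max_theta = 2 * pi / 180,
                            theta_step = 0.05 * pi / 180,
                            min_confidence = 0.2) {
  stopifnot(length(mosaics) >= 1L)
  dm <- dim(mosaics[[reference]])
  stopifnot(all(vapply(mosaics, function(m) all(dim(m) == dm), TRUE)))
  ref <- mosaics[[reference]]
  lapply(seq_along(mosaics), function(cc) {
    if (cc == reference) return(rigid_transform(reference = reference))
    mov <- mosaics[[cc]]
    score <- function(theta) {
      b <- if (theta == 0) mov else rotate_image(mov, theta)
      phase_correlate(ref, b)$peak
    }
    best_theta <- 0
    if (max_theta > 0) {
      grid <- seq(-max_theta, max_theta, by = theta_step)
      peaks <- vapply(grid, score, numeric(1))
      k <- which.max(peaks)
      lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
      opt <- stats::optimize(score, c(lo, hi), maximum = TRUE,
                             tol = theta_step / 20)
      best_theta <- opt$maximum
    }
    b <- if (best_theta == 0) mov else rotate_image(mov, best_theta)
    pc <- phase_correlate(ref, b)
    if (pc$peak < min_confidence)
      stop(errorCondition(
        sprintf("registration failed for cycle %d: correlation peak %.4f below %.4f",
                cc, pc$peak, min_confidence),
        class = c("cycifer_registration_error", "error", "condition")))
    # de-rotating the moving mosaic by -theta turned the residual motion into
    # a pure shift s = R(-theta) t; undo the rotation to report t
    ct <- cos(best_theta); st <- sin(best_theta)
    rigid_transform(dx = ct * pc$dx - st * pc$dy,
                    dy = st * pc$dx + ct * pc$dy,
                    theta = best_theta, reference = reference)
  })
}

#' Resample all cycles into the reference frame
#'
#' Every channel of cycle `c` is sampled through that cycle's rigid
#' transform with bilinear interpolation; pixels that fall outside the
#' source mosaic are marked invalid and excluded downstream.
#'
#' @param mosaics nested list: `mosaics[[cycle]][[channel]]`, equal shapes.
#' @param transforms per-cycle [rigid_transform()]s from [register_cycles()].
#' @return object of class `CycleStack`: `data` array indexed
#'   `[cycle, channel, y, x]`, `valid` array `[cycle, y, x]`, `transforms`,
#'   and `provenance`.
#' @export
assemble_stack <- function(mosaics, transforms) {
  n_cyc <- length(mosaics)
  stopifnot(length(transforms) == n_cyc)
  n_chan <- length(mosaics[[1]])
  dm <- dim(mosaics[[1]][[1]])
  for (cc in seq_len(n_cyc))
    for (k in seq_len(length(mosaics[[cc]])))
      if (!all(dim(mosaics[[cc]][[k]]) == dm))
        stop("mosaic shape mismatch at cycle ", cc, " channel ", k - 1)
  H <- dm[1]; W <- dm[2]
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  data <- array(NA_real_, c(n_cyc, n_chan, H, W))
  valid <- array(FALSE, c(n_cyc, H, W))
  g <- expand.grid(y = 0:(H - 1), x = 0:(W - 1))
  for (cc in seq_len(n_cyc)) {
    tr <- transforms[[cc]]
    if (tr$dx == 0 && tr$dy == 0 && tr$theta == 0) {
      for (k in seq_len(n_chan)) data[cc, k, , ] <- mosaics[[cc]][[k]]
      valid[cc, , ] <- TRUE
      next
    }
    q <- apply_transform(tr, cbind(g$x, g$y), ctr)
    ok <- matrix(q[, 1] >= 0 & q[, 1] <= W - 1 & q[, 2] >= 0 & q[, 2] <= H - 1,
                 H, W)
    for (k in seq_len(n_chan)) {
      v <- bilinear_sample(mosaics[[cc]][[k]], q[, 1], q[, 2])
      data[cc, k, , ] <- matrix(v, H, W)
    }
    valid[cc, , ] <- ok & !is.na(matrix(data[cc, 1, , ], H, W))
  }
  structure(list(data = data, valid = valid, transforms = transforms,
                 dim = c(cycles = n_cyc, channels = n_chan,
                         height = H, width = W),
                 provenance = list(assembled = TRUE)),
            class = "CycleStack")
}

#' @export
print.CycleStack <- function(x, ...) {
  cat(sprintf("CycleStack: %d cycles x %d channels, %dx%d px (%.1f%% valid)\n",
              x$dim["cycles"], x$dim["channels"], x$dim["width"],
              x$dim["height"], 100 * mean(x$valid)))
  invisible(x)
}
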