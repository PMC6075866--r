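# Internal helpers shared across modules.
#
# Images are plain numeric matrices indexed [y + 1, x + 1]: row = y, col = x,
# origin at the top-left pixel, 0-based coordinates in all user-facing tables.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers do not perturb the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Trapezoidal integral of y over x (x ascending).
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Otsu threshold of a numeric vector (maximizes between-class variance on a
# fixed-width histogram). Returns a value strictly between two populated bins.
otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (length(v) < 2L || diff(range(v)) == 0)
    stop("otsu_threshold: input has no contrast")
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- as.numeric(tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                        all.inside = TRUE), nbins = levels))
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[levels]
  mt <- m[levels]
  w1 <- w[-levels]; m1 <- m[-levels]
  between <- ifelse(w1 == 0 | w1 == n, 0,
                    (mt * w1 - m1 * n)^2 / (w1 * (n - w1) * n))
  k <- which.max(between)
  breaks[k + 1L]
}

# Grayscale morphology wrappers: EBImage erode/dilate operate correctly only
# on [0, 1]-ranged data (values outside are clipped), so rescale around them.
gray_morph <- function(img, brush, op = c("erode", "dilate")) {
  op <- match.arg(op)
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(img)
  scaled <- (img - lo) / (hi - lo)
  out <- if (op == "erode") EBImage::erode(scaled, brush)
         else EBImage::dilate(scaled, brush)
  matrix(as.numeric(out), nrow(img), ncol(img)) * (hi - lo) + lo
}

disc_brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")

# Bilinear sampling of matrix `img` at continuous 0-based coordinates
# (xs, ys). Points outside the support return NA.
bilinear_sample <- function(img, xs, ys) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= w - 1 & y0 <= h - 1 &
        (x0 + (fx > 0)) <= w - 1 & (y0 + (fy > 0)) <= h - 1
  out <- rep(NA_real_, length(xs))
  if (!any(ok)) return(out)
  x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
  x1k <- pmin(x0k + 1, w - 1); y1k <- pmin(y0k + 1, h - 1)
  i00 <- y0k + 1 + x0k * h; i10 <- y1k + 1 + x0k * h
  i01 <- y0k + 1 + x1k * h; i11 <- y1k + 1 + x1k * h
  out[ok] <- img[i00] * (1 - fxk) * (1 - fyk) + img[i10] * (1 - fxk) * fyk +
             img[i01] * fxk * (1 - fyk) + img[i11] * fxk * fyk
  out
}

# Clip helper.
clip0 <- function(x) pmax(x, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deep-merge override list into defaults, rejecting unknown keys.
merge_config <- function(defaults, overrides, path = "") {
  if (is.null(overrides)) return(defaults)
  stopifnot(is.list(overrides))
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     paste0(path, nm, "$"))
    else defaults[[nm]] <- overrides[[nm]]
  }
  defaults
}
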