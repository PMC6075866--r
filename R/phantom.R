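#' Default tissue-phantom parameters
#'
#' Parameters describing the synthetic tissue used throughout the package:
#' a dense field of non-overlapping nuclei partitioned into a tumor and a
#' stromal region, with per-cluster lognormal marker expression and a
#' configurable per-cycle cell-dropout schedule.
#'
#' The default panel carries nine markers imaged over three four-channel
#' cycles (channel 0 of every cycle is the nuclear stain). Cells belong to
#' one of three expression clusters (immune-like, tumor-like, stromal-like);
#' cluster frequencies differ between the two regions and the stromal marker
#' aSMA is additionally up-weighted in the stromal region, mimicking the
#' smooth-muscle-actin contrast used to delineate tumor from stroma.
#'
#' @param ... named overrides of the defaults (unknown names are an error).
#' @return a list of phantom parameters.
#' @export
phantom_config <- function(...) {
  markers <- c("CD3", "CD8", "aSMA", "PD1", "PDL1", "S100", "CD45", "pRB", "VEGFR2")
  base <- 4.0   # lognormal meanlog of a marker in non-expressing cells (~55 au)
  high <- 6.5   # meanlog in expressing cells (~665 au)
  meanlog <- matrix(base, 3, length(markers),
                    dimnames = list(c("immune", "tumor", "stromal"), markers))
  meanlog["immune",  c("CD3", "CD8", "CD45", "PD1")] <- high
  meanlog["tumor",   c("S100", "pRB", "PDL1")]       <- high
  meanlog["stromal", c("aSMA", "VEGFR2")]            <- high
  defaults <- list(
    n_cells = 500L,
    canvas = c(480L, 480L),          # (width, height) px
    pixel_size = 0.65,               # um per px (10X slide scanner scale)
    nuclear_radius_mean = 5,
    nuclear_radius_sd = 0.4,
    hardcore_factor = 1.5,           # centers >= factor * max(r_i, r_j) apart
    K = 3L,
    markers = markers,
    expression_meanlog = meanlog,
    expression_sdlog = 0.35,
    region = list(type = "halfplane", frac = 0.5),
    region_cluster_weights = matrix(
      c(0.45, 0.45, 0.10,
        0.25, 0.10, 0.65), 2, 3, byrow = TRUE,
      dimnames = list(c("tumor", "stroma"), c("immune", "tumor", "stromal"))),
    marker_region_factor = list(aSMA = c(tumor = 1, stroma = 8)),
    dropout = list(rate = 0.15, cycles = 2:10, density_bias = 1,
                   bias_radius = 30)
  )
  merge_config(defaults, list(...))
}

#' Generate a ground-truth tissue phantom
#'
#' Places nuclei by dart throwing under a hard-core constraint, assigns each
#' cell a region (from the stored region mask) and an expression cluster,
#' draws per-cluster lognormal marker expression, and samples a spatially
#' biased dropout cycle per cell (the cycle at which the cell detaches from
#' the slide; `NA` for cells that persist). Dropout is biased toward cells
#' with few neighbours, reflecting the preferential loss of low-cellularity
#' tissue across staining cycles.
#'
#' @param config parameter list from [phantom_config()].
#' @param seed integer seed; output is fully determined by `(config, seed)`.
#' @return an object of class `TissuePhantom`: a list with `cells`
#'   (data.frame: cell_id, x, y, radius, region, cluster, dropout_cycle),
#'   `expression` (cells x markers matrix), `region_mask` (canvas matrix of
#'   region names), `canvas`, `pixel_size` and `config`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  cf <- config
  K <- cf$K
  stopifnot(K >= 1L, cf$hardcore_factor > 0)
  w <- as.integer(cf$canvas[1]); h <- as.integer(cf$canvas[2])
  rcw <- cf$region_cluster_weights
  if (any(abs(rowSums(rcw) - 1) > 1e-8))
    stop("region_cluster_weights rows must sum to 1")

  region_mask <- make_region_mask(cf$region, w, h)
  n <- as.integer(cf$n_cells)
  markers <- cf$markers

  with_seed(seed, {
    ## -- placement: dart throwing with hard-core rejection ----------------
    xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
    attempts <- 0L
    max_attempts <- max(10L * n, 100L)
    while (length(xs) < n) {
      if (attempts >= max_attempts)
        stop(errorCondition(
          sprintf("phantom placement failed: %d of %d cells placed in %d attempts (density infeasible under hard-core constraint)",
                  length(xs), n, attempts),
          class = c("cycifer_placement_error", "error", "condition")))
      attempts <- attempts + 1L
      r <- max(2, stats::rnorm(1, cf$nuclear_radius_mean, cf$nuclear_radius_sd))
      x <- stats::runif(1, r, w - 1 - r)
      y <- stats::runif(1, r, h - 1 - r)
      if (length(xs)) {
        d2 <- (xs - x)^2 + (ys - y)^2
        minsep <- cf$hardcore_factor * pmax(rs, r)
        if (any(d2 < minsep^2)) next
      }
      xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
    }

    region <- if (n) region_mask[cbind(floor(ys) + 1, floor(xs) + 1)] else character(0)

    ## -- cluster assignment, region-dependent frequencies -----------------
    cluster <- integer(n)
    for (rg in rownames(rcw)) {
      idx <- which(region == rg)
      if (length(idx))
        cluster[idx] <- sample.int(K, length(idx), replace = TRUE, prob = rcw[rg, ])
    }

    ## -- lognormal expression ---------------------------------------------
    ml <- cf$expression_meanlog
    expr <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
    if (n)
      for (m in seq_along(markers))
        expr[, m] <- stats::rlnorm(n, ml[cluster, m], cf$expression_sdlog)
    for (mk in names(cf$marker_region_factor)) {
      fac <- cf$marker_region_factor[[mk]]
      if (mk %in% markers && n)
        expr[, mk] <- expr[, mk] * fac[region]
    }

    ## -- spatially biased dropout -----------------------------------------
    dropout_cycle <- rep(NA_integer_, n)
    n_drop <- if (n) stats::rbinom(1, n, cf$dropout$rate) else 0L
    if (n_drop > 0) {
      br2 <- cf$dropout$bias_radius^2
      nb <- vapply(seq_len(n), function(i)
        sum((xs - xs[i])^2 + (ys - ys[i])^2 <= br2) - 1L, integer(1))
      wgt <- (1 / (1 + nb))^cf$dropout$density_bias
      victims <- sample.int(n, n_drop, prob = wgt)
      dropout_cycle[victims] <- sample(cf$dropout$cycles, n_drop, replace = TRUE)
    }

    cells <- data.frame(
      cell_id = seq_len(n), x = xs, y = ys, radius = rs,
      region = region, cluster = cluster,
      dropout_cycle = dropout_cycle, stringsAsFactors = FALSE)

    structure(list(cells = cells, expression = expr,
                   region_mask = region_mask,
                   canvas = c(width = w, height = h),
                   pixel_size = cf$pixel_size, config = cf),
              class = "TissuePhantom")
  })
}

# Region mask: canvas-shaped character matrix partitioning the canvas.
make_region_mask <- function(region, w, h) {
  if (!identical(region$type, "halfplane"))
    stop("unsupported region type: ", region$type)
  split_col <- floor(region$frac * w)
  mask <- matrix("tumor", h, w)
  if (split_col >= 1) mask[, seq_len(split_col)] <- "stroma"
  mask
}

#' @export
print.TissuePhantom <- function(x, ...) {
  cat(sprintf("TissuePhantom: %d cells on %dx%d px canvas (%.2f um/px)\n",
              nrow(x$cells), x$canvas["width"], x$canvas["height"], x$pixel_size))
  cat(sprintf("  markers: %s\n", paste(colnames(x$expression), collapse = ", ")))
  cat(sprintf("  clusters: %d; dropout: %d cells\n",
              x$config$K, sum(!is.na(x$cells$dropout_cycle))))
  invisible(x)
}
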