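test_that("rigid transforms compose and invert to identity", {
  tr <- rigid_transform(dx = 3.7, dy = -1.2, theta = 0.4 * pi / 180)
  id <- compose_transform(tr, invert_transform(tr))
  expect_lt(abs(id$dx), 1e-9)
  expect_lt(abs(id$dy), 1e-9)
  expect_lt(abs(id$theta), 1e-12)
  xy <- cbind(c(0, 10, 33.3), c(5, -2, 7.1))
  ctr <- c(50, 50)
  back <- apply_transform(invert_transform(tr),
                          apply_transform(tr, xy, ctr), ctr)
  expect_equal(back, xy, tolerance = 1e-9)
})

test_that("shading estimation recovers a flat field from constant tiles", {
  tiles <- replicate(10, matrix(37, 64, 64), simplify = FALSE)
  sh <- estimate_shading(tiles)
  expect_equal(sh$flatfield, matrix(1, 64, 64), tolerance = 1e-6)
  expect_lt(abs(mean(sh$flatfield) - 1), 1e-6)
  expect_true(all(sh$flatfield > 0))
  expect_error(estimate_shading(tiles[1:7]), ">= 8")
})

test_that("shading estimation recovers the generating illumination field", {
  # a 4x4 grid gives sixteen distinct cell layouts for the per-pixel median
  cf <- small_phantom_config(n = 80, canvas = 416L)
  ph <- generate_phantom(cf, seed = 3)
  acq <- acquisition_model(
    grid = c(rows = 4L, cols = 4L), tile = c(width = 128L, height = 128L),
    overlap = 0.25, n_cycles = 1L, offsets = matrix(0, 1, 3),
    shading = list(amplitude = 0.3), af = list(amplitude = 100, decay = 0.7),
    noise = list(photons_per_count = 0.5, read_sd = 1))
  ts <- render_cycles(ph, acq, seed = 1)
  ch0 <- ts$tiles[ts$index$name[ts$index$channel == 0]]
  sh <- estimate_shading(ch0)
  truth <- shading_field(acq)
  expect_gt(stats::cor(as.vector(sh$flatfield), as.vector(truth)), 0.99)
})

test_that("median flatfield ignores sparse bright cells", {
  set.seed(11)
  tiles <- lapply(1:12, function(i)
    matrix(100, 96, 96) +
      render_spots(96, 96, runif(1, 10, 85), runif(1, 10, 85), 5, 3000))
  sh <- estimate_shading(tiles)
  expect_lt(max(abs(sh$flatfield - 1)), 0.05)
})

test_that("tile correction divides out shading exactly", {
  sh <- estimate_shading(replicate(8, matrix(10, 32, 32), simplify = FALSE))
  img <- matrix(runif(32 * 32, 0, 100), 32, 32)
  expect_equal(correct_tile(img, sh), img, tolerance = 1e-9)
  s <- 1 + 0.2 * outer(sin(seq(0, pi, length.out = 32)),
                       cos(seq(0, pi, length.out = 32)))
  s <- s / mean(s)
  model <- structure(list(flatfield = s, darkfield = matrix(0, 32, 32)),
                     class = "ShadingModel")
  expect_equal(correct_tile(s, model), matrix(1, 32, 32), tolerance = 1e-12)
  expect_error(correct_tile(matrix(1, 16, 16), model), "shape")
})

test_that("shading correction reduces background CV on shaded synthetic tiles", {
  ph <- generate_phantom(small_phantom_config(n = 0, canvas = 168L), seed = 1)
  acq <- acquisition_model(
    grid = c(rows = 2L, cols = 2L), tile = c(width = 96L, height = 96L),
    overlap = 0.25, n_cycles = 2L, offsets = matrix(0, 2, 3),
    shading = list(amplitude = 0.35), af = list(amplitude = 200, decay = 1),
    noise = list(photons_per_count = 0.5, read_sd = 1))
  ts <- render_cycles(ph, acq, seed = 2)
  tiles <- ts$tiles[ts$index$name[ts$index$channel == 1]]
  sh <- estimate_shading(tiles)
  cv <- function(x) stats::sd(x) / mean(x)
  for (t in tiles)
    expect_lt(cv(correct_tile(t * 1.0, sh)), cv(t))
})

test_that("rolling-ball subtraction flattens background and keeps small features", {
  expect_equal(subtract_background(matrix(7, 120, 120), 50),
               matrix(0, 120, 120))
  d <- matrix(10, 120, 120); d[60:62, 60:62] <- 10 + 55
  out <- subtract_background(d, 50)
  expect_lt(abs(max(out) - 55) / 55, 0.05)
  expect_equal(out[5, 5], 0)
  expect_error(subtract_background(matrix(0, 40, 40), 40), "too large")
  expect_error(subtract_background(matrix(0, 40, 40), 0.5), "radius")
})

test_that("rolling ball agrees with brute-force grayscale opening", {
  set.seed(4)
  img <- matrix(runif(48 * 48, 0, 50), 48, 48) +
    outer(seq(0, 30, length.out = 48), seq(0, 20, length.out = 48), "+")
  r <- 6
  brush <- as.matrix(EBImage::makeBrush(2 * r + 1, "disc")) > 0
  brute_open <- function(im) {
    h <- nrow(im); w <- ncol(im)
    ero <- matrix(NA_real_, h, w); dil <- matrix(NA_real_, h, w)
    for (y in 1:h) for (x in 1:w) {
      ys <- max(1, y - r):min(h, y + r); xs <- max(1, x - r):min(w, x + r)
      bb <- brush[ys - y + r + 1, xs - x + r + 1, drop = FALSE]
      ero[y, x] <- min(im[ys, xs][bb])
    }
    for (y in 1:h) for (x in 1:w) {
      ys <- max(1, y - r):min(h, y + r); xs <- max(1, x - r):min(w, x + r)
      bb <- brush[ys - y + r + 1, xs - x + r + 1, drop = FALSE]
      dil[y, x] <- max(ero[ys, xs][bb])
    }
    dil
  }
  mine <- subtract_background(img, r)
  oracle <- pmax(img - brute_open(img), 0)
  interior <- (r + 1):(48 - r)
  expect_equal(mine[interior, interior], oracle[interior, interior],
               tolerance = 1e-9)
  # slowly varying ramp: residual well below the ramp range
  ramp <- outer(seq(0, 100, length.out = 120), rep(1, 120))
  res <- subtract_background(ramp, 20)
  expect_lt(max(res[30:90, 30:90]), 0.05 * 100)
})

test_that("unsharp masking is identity at amount 0 and sharpens edges", {
  img <- matrix(runif(40 * 40), 40, 40)
  expect_identical(unsharp_mask(img, 2, 0), img)
  expect_equal(unsharp_mask(matrix(5, 40, 40), 3, 0.8), matrix(5, 40, 40),
               tolerance = 1e-6)
  step <- cbind(matrix(10, 40, 20), matrix(100, 40, 20))
  sharp <- unsharp_mask(step, 2, 0.7)
  grad <- function(m) max(abs(diff(t(m))))
  expect_gt(grad(sharp), grad(step))
  expect_error(unsharp_mask(step, 2, 1.5), "amount")
})

test_that("stitching reconstructs a mosaic cut at exact nominal offsets", {
  ph <- generate_phantom(small_phantom_config(n = 120, canvas = 300L), seed = 5)
  acq <- clean_acq(n_cycles = 1L, tile = 180L,
                   grid = c(rows = 2L, cols = 2L), overlap = 1 / 3)
  ts <- render_cycles(ph, acq, seed = 1)
  sel <- ts$index[ts$index$channel == 0, ]
  st <- stitch_grid(lapply(ts$tiles[sel$name], function(t) t * 1.0),
                    sel, tile_layout(acq)$stride)
  ideal <- round(ts$ideal[[1]][[1]])
  expect_equal(dim(st$mosaic), dim(ideal))
  expect_lt(max(abs(st$mosaic - ideal)), 1e-9)
  expect_lt(max(abs(st$offsets$ox_refined - st$offsets$ox)), 0.25)
})

test_that("stitching recovers jittered tile origins within half a pixel", {
  set.seed(9)
  scene <- render_spots(340, 340, runif(170, 10, 330), runif(170, 10, 330),
                        rep(5, 170), runif(170, 500, 3000))
  tile <- 160L; stride <- c(x = 120L, y = 120L)
  index <- expand.grid(row = 0:1, col = 0:1)
  index$ox <- index$col * stride[["x"]]; index$oy <- index$row * stride[["y"]]
  jit <- cbind(sample(-3:3, 4, TRUE), sample(-3:3, 4, TRUE))
  jit[1, ] <- 0  # anchor tile cut at its nominal origin
  margin <- 5L   # keeps jittered cuts inside the scene
  tiles <- lapply(1:4, function(i) {
    ox <- margin + index$ox[i] + jit[i, 1]
    oy <- margin + index$oy[i] + jit[i, 2]
    scene[(oy + 1):(oy + tile), (ox + 1):(ox + tile)]
  })
  st <- stitch_grid(tiles, index, stride)
  expect_lt(max(abs((st$offsets$ox_refined - index$ox[1]) -
                    (index$ox + jit[, 1]))), 0.5)
  expect_lt(max(abs((st$offsets$oy_refined - index$oy[1]) -
                    (index$oy + jit[, 2]))), 0.5)
})

test_that("single-tile stitching returns the tile; featureless overlaps fall back", {
  tile <- matrix(runif(64 * 64), 64, 64)
  st <- stitch_grid(list(tile), data.frame(row = 0, col = 0, ox = 0, oy = 0),
                    c(x = 40, y = 40))
  expect_identical(st$mosaic, tile)
  flat <- replicate(4, matrix(5, 64, 64), simplify = FALSE)
  index <- expand.grid(row = 0:1, col = 0:1)
  index$ox <- index$col * 40L; index$oy <- index$row * 40L
  st2 <- stitch_grid(flat, index, c(x = 40, y = 40))
  expect_gt(length(st2$warnings), 0)
  expect_equal(st2$offsets$ox_refined, index$ox)
  expect_error(stitch_grid(flat, index, c(x = 60, y = 60)), ">= 20 px")
})

test_that("cycle registration recovers synthetic rigid offsets", {
  cf <- small_phantom_config(n = 140, canvas = 360L)
  ph <- generate_phantom(cf, seed = 8)
  acq <- clean_acq(n_cycles = 3L, tile = 360L,
                   offsets = rbind(c(0, 0, 0),
                                   c(5, -3, 0),
                                   c(-2, 4, 0.5 * pi / 180)))
  ts <- render_cycles(ph, acq, seed = 1)
  mos <- lapply(ts$ideal, `[[`, 1)
  # identical mosaics give identity transforms
  same <- register_cycles(list(mos[[1]], mos[[1]]), max_theta = 0)
  expect_equal(same[[2]]$dx, 0, tolerance = 0.05)
  expect_equal(same[[2]]$dy, 0, tolerance = 0.05)
  trs <- register_cycles(mos)
  truth <- ts$manifest$transforms
  for (cc in 2:3) {
    expect_lt(abs(trs[[cc]]$dx - truth$dx[cc]), 0.5)
    expect_lt(abs(trs[[cc]]$dy - truth$dy[cc]), 0.5)
    expect_lt(abs(trs[[cc]]$theta - truth$theta[cc]), 0.1 * pi / 180)
  }
})

test_that("registration fails loudly on uncorrelated images", {
  set.seed(3)
  a <- matrix(rnorm(200 * 200), 200, 200)
  b <- matrix(rnorm(200 * 200), 200, 200)
  expect_error(register_cycles(list(a, b), max_theta = 0),
               class = "cycifer_registration_error")
})

test_that("stack assembly aligns shifted cycles within interpolation tolerance", {
  # band-limited scene so interpolation error is the only discrepancy
  set.seed(12)
  base <- as.matrix(EBImage::gblur(matrix(runif(300 * 300, 0, 1000),
                                          300, 300), 3))
  tr <- rigid_transform(dx = 3.4, dy = -2.2)
  g <- expand.grid(y = 0:299, x = 0:299)
  ctr <- c(299 / 2, 299 / 2)
  q <- apply_transform(invert_transform(tr), cbind(g$x, g$y), ctr)
  shifted <- matrix(cycifer:::bilinear_sample(base, q[, 1], q[, 2]), 300, 300)
  shifted[is.na(shifted)] <- 0
  mosaics <- list(list(base), list(shifted))
  # identity transforms reproduce the input planes exactly
  st0 <- assemble_stack(mosaics, list(rigid_transform(), rigid_transform()))
  expect_equal(matrix(st0$data[2, 1, , ], 300, 300), shifted)
  trs <- register_cycles(list(base, shifted), max_theta = 0)
  expect_lt(abs(trs[[2]]$dx - 3.4), 0.1)
  expect_lt(abs(trs[[2]]$dy + 2.2), 0.1)
  st <- assemble_stack(mosaics, trs)
  ref <- matrix(st$data[1, 1, , ], 300, 300)
  ali <- matrix(st$data[2, 1, , ], 300, 300)
  ok <- as.logical(st$valid[2, , ])
  diffs <- abs(ref[ok] - ali[ok])
  expect_lt(unname(stats::quantile(diffs, 0.99)), 0.02 * diff(range(ref)))
})

test_that("an out-of-frame cycle yields an empty, crash-free cell table", {
  cf <- small_phantom_config(n = 40, canvas = 200L)
  ph <- generate_phantom(cf, seed = 2)
  acq <- clean_acq(n_cycles = 2L, tile = 200L, offsets = matrix(0, 2, 3))
  ts <- render_cycles(ph, acq, seed = 1)
  st <- assemble_stack(ts$ideal, list(rigid_transform(),
                                      rigid_transform(dx = 1e4, dy = 1e4)))
  expect_false(any(st$valid[2, , ]))
  nuc <- matrix(st$data[1, 1, , ], 200, 200)
  labels <- split_nuclei(binarize_nuclei(nuc), 5)
  comp <- expand_cytoplasm(labels, 3)
  ct <- quantify(list(nucleus = labels, cell = comp$cell,
                      cytoplasm = comp$cytoplasm), st)
  expect_true(all(is.na(ct$cyc2_ch0_nuc_mean)))
  expect_false(any(ct$valid))
})

test_that("preprocessing is reproducible on identical inputs", {
  set.seed(21)
  tiles <- replicate(4, matrix(runif(96 * 96, 0, 1000), 96, 96),
                     simplify = FALSE)
  index <- expand.grid(row = 0:1, col = 0:1)
  index$ox <- index$col * 64L; index$oy <- index$row * 64L
  a <- stitch_grid(tiles, index, c(x = 64, y = 64))
  b <- stitch_grid(tiles, index, c(x = 64, y = 64))
  expect_identical(a, b)
})
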