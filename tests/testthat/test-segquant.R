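disk_mask <- function(size, cx, cy, r) {
  g <- expand.grid(y = 0:(size - 1), x = 0:(size - 1))
  matrix(sqrt((g$x - cx)^2 + (g$y - cy)^2) <= r, size, size)
}

test_that("Otsu binarization recovers a bimodal foreground exactly", {
  truth <- disk_mask(80, 30, 40, 10) | disk_mask(80, 60, 20, 8)
  img <- matrix(100, 80, 80); img[truth] <- 1000
  expect_identical(binarize_nuclei(img), truth)
  expect_error(binarize_nuclei(matrix(0, 40, 40)),
               class = "cycifer_threshold_error")
  expect_error(binarize_nuclei(matrix(7, 40, 40)),
               class = "cycifer_threshold_error")
})

test_that("binarization fills small holes and removes specks", {
  truth <- disk_mask(60, 30, 30, 12)
  img <- matrix(50, 60, 60); img[truth] <- 800
  img[30, 30] <- 50                     # 1-px hole
  img[5, 5] <- 800                      # 1-px speck (< min_area)
  mask <- binarize_nuclei(img)
  expect_true(mask[30, 30])
  expect_false(mask[5, 5])
})

test_that("binarized foreground area matches summed true disk areas", {
  cf <- small_phantom_config(n = 200, canvas = 480L)
  ph <- generate_phantom(cf, seed = 4)
  acq <- clean_acq(tile = 480L)
  ts <- render_cycles(ph, acq, seed = 1)
  mask <- binarize_nuclei(ts$ideal[[1]][[1]])
  truth_area <- sum(pi * ph$cells$radius^2)
  expect_lt(abs(sum(mask) - truth_area) / truth_area, 0.10)
})

test_that("watershed splits touching nuclei along the equidistance line", {
  one <- disk_mask(60, 30, 30, 10)
  lab1 <- split_nuclei(one, 5)
  expect_equal(max(lab1), 1)
  expect_equal(sum(lab1 > 0), sum(one))

  r <- 10; centers <- c(25, 25 + 1.8 * r)   # overlap by 20% of the radius
  two <- disk_mask(70, centers[1], 35, r) | disk_mask(70, centers[2], 35, r)
  lab2 <- split_nuclei(two, 8)
  expect_equal(max(lab2), 2)
  g <- expand.grid(y = 0:69, x = 0:69)
  d1 <- matrix(sqrt((g$x - centers[1])^2 + (g$y - 35)^2), 70, 70)
  d2 <- matrix(sqrt((g$x - centers[2])^2 + (g$y - 35)^2), 70, 70)
  left_label <- lab2[36, 26]
  mis <- (lab2 == left_label & d1 > d2 + 1) |
         (lab2 > 0 & lab2 != left_label & d2 > d1 + 1)
  expect_equal(sum(mis), 0)
  expect_equal(max(split_nuclei(matrix(FALSE, 20, 20), 5)), 0)
})

test_that("nucleus count on a clean phantom is within 5% of truth", {
  cf <- small_phantom_config(n = 150, canvas = 400L)
  ph <- generate_phantom(cf, seed = 6)
  ts <- render_cycles(ph, clean_acq(tile = 400L), seed = 1)
  lab <- split_nuclei(binarize_nuclei(ts$ideal[[1]][[1]]), 5)
  expect_lt(abs(max(lab) - 150) / 150, 0.05)
})

test_that("cytoplasm expansion matches brute-force nearest-nucleus geometry", {
  nuc <- disk_mask(40, 20, 20, 6)
  labels <- matrix(0L, 40, 40); labels[nuc] <- 1L
  comp <- expand_cytoplasm(labels, 3)
  # oracle: pixels within 3 px (Euclidean) of any nucleus pixel
  fg <- which(nuc)
  fy <- (fg - 1) %% 40; fx <- (fg - 1) %/% 40
  g <- expand.grid(y = 0:39, x = 0:39)
  mind <- apply(cbind(g$x, g$y), 1, function(p)
    sqrt(min((fx - p[1])^2 + (fy - p[2])^2)))
  oracle <- matrix(mind <= 3, 40, 40)
  expect_identical(comp$cell > 0, oracle)
  expect_equal(sum(comp$cytoplasm > 0), sum(oracle) - sum(nuc))
  # nucleus within cell; cytoplasm disjoint from nucleus
  expect_true(all(comp$cell[nuc] == 1L))
  expect_true(all(comp$cytoplasm[nuc] == 0L))
})

test_that("competing nuclei halt expansion at the equidistance boundary", {
  m1 <- disk_mask(60, 22, 30, 5); m2 <- disk_mask(60, 36, 30, 5)  # 4 px gap
  labels <- matrix(0L, 60, 60); labels[m1] <- 1L; labels[m2] <- 2L
  comp <- expand_cytoplasm(labels, 6)
  expect_equal(sort(unique(as.vector(comp$cell))), c(0L, 1L, 2L))
  d1 <- matrix(sqrt(outer((0:59 - 30)^2, (0:59 - 22)^2, "+")), 60, 60)
  d2 <- matrix(sqrt(outer((0:59 - 30)^2, (0:59 - 36)^2, "+")), 60, 60)
  mis <- (comp$cell == 1L & d1 > d2 + 1.5) | (comp$cell == 2L & d2 > d1 + 1.5)
  expect_equal(sum(mis), 0)
})

test_that("cytoplasm expansion distance follows the objective convention", {
  expect_identical(expansion_pixels("10X"), 3L)
  expect_identical(expansion_pixels("40X"), 6L)
})

test_that("quantification of a uniform disk is exact", {
  nuc <- disk_mask(50, 25, 25, 8)
  labels <- matrix(0L, 50, 50); labels[nuc] <- 1L
  comp <- expand_cytoplasm(labels, 3)
  plane <- matrix(0, 50, 50); plane[comp$cell > 0] <- 42
  stack <- assemble_stack(list(list(plane)), list(rigid_transform()))
  ct <- quantify(list(nucleus = labels, cell = comp$cell,
                      cytoplasm = comp$cytoplasm), stack)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$cyc1_ch0_nuc_mean, 42)
  expect_equal(ct$cyc1_ch0_nuc_int, 42 * sum(nuc))
  expect_equal(ct$cyc1_ch0_cell_int, 42 * ct$cell_area)
  expect_equal(ct$nucleus_area, sum(nuc))
  expect_equal(ct$centroid_x, 25, tolerance = 0.05)
})

test_that("integrated intensity is exactly mean times area in every row", {
  cf <- small_phantom_config(n = 60, canvas = 240L)
  ph <- generate_phantom(cf, seed = 3)
  stack <- clean_stack(ph, clean_acq(n_cycles = 3L, tile = 240L,
                                     offsets = matrix(0, 3, 3)))
  labels <- split_nuclei(binarize_nuclei(
    matrix(stack$data[1, 1, , ], 240, 240)), 5)
  comp <- expand_cytoplasm(labels, 3)
  ct <- quantify(list(nucleus = labels, cell = comp$cell,
                      cytoplasm = comp$cytoplasm), stack)
  for (cc in 1:3) for (k in 0:3) {
    m <- ct[[sprintf("cyc%d_ch%d_nuc_mean", cc, k)]]
    i <- ct[[sprintf("cyc%d_ch%d_nuc_int", cc, k)]]
    expect_equal(i, m * ct$nucleus_area, tolerance = 1e-12)
    mc <- ct[[sprintf("cyc%d_ch%d_cell_mean", cc, k)]]
    ic <- ct[[sprintf("cyc%d_ch%d_cell_int", cc, k)]]
    expect_equal(ic, mc * ct$cell_area, tolerance = 1e-12)
  }
})

test_that("per-cell marker means track true expression on a noiseless phantom", {
  cf <- small_phantom_config(n = 120, canvas = 360L)
  ph <- generate_phantom(cf, seed = 10)
  stack <- clean_stack(ph, clean_acq(n_cycles = 3L, tile = 360L,
                                     offsets = matrix(0, 3, 3)))
  labels <- split_nuclei(binarize_nuclei(
    matrix(stack$data[1, 1, , ], 360, 360)), 5)
  comp <- expand_cytoplasm(labels, 3)
  ct <- quantify(list(nucleus = labels, cell = comp$cell,
                      cytoplasm = comp$cytoplasm), stack)
  scores <- segmentation_scores(ph$cells, ct)
  expect_gte(scores$recall, 0.9)
  expect_gte(scores$precision, 0.9)
  d2 <- outer(ph$cells$x, ct$centroid_x, "-")^2 +
        outer(ph$cells$y, ct$centroid_y, "-")^2
  nn <- apply(d2, 1, which.min)
  hit <- sqrt(d2[cbind(seq_len(nrow(ph$cells)), nn)]) <= ph$cells$radius
  mm <- marker_matrix(ct, marker_channel_map(colnames(ph$expression)),
                      compartment = "nuc")
  for (m in colnames(ph$expression)) {
    rho <- stats::cor(ph$expression[hit, m], mm[nn[hit], m],
                      method = "spearman", use = "complete.obs")
    expect_gt(rho, 0.95)
  }
})

test_that("empty label input yields an empty table with the full schema", {
  labels <- matrix(0L, 30, 30)
  stack <- assemble_stack(list(list(matrix(0, 30, 30))),
                          list(rigid_transform()))
  ct <- quantify(list(nucleus = labels, cell = labels, cytoplasm = labels),
                 stack)
  expect_equal(nrow(ct), 0)
  expect_true(all(c("cell_id", "centroid_x", "nucleus_area", "valid",
                    "cyc1_ch0_nuc_mean", "cyc1_ch0_cell_int") %in% names(ct)))
})
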