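# End-to-end orchestration: configuration, stage execution, provenance.
#
# Stages run in dependency order (simulate -> prep -> segment -> qc ->
# phenotype -> spatial) and communicate only through documented files in
# the output directory, so any suffix of the chain can be re-run.

#' Default run configuration
#'
#' All analysis defaults follow the published protocol values: rolling-ball
#' radius 50 px; cytoplasm expansion 3 px (10X) or 6 px (40X); dynamic
#' range from the 5th/95th percentiles; channel normalization to the
#' 1st/99th percentiles; EMGM with 30 restarts; t-SNE perplexity 30; kNN
#' density with k = 4; 1000 cells per entropy field; 100 bootstrap rounds.
#'
#' @param overrides nested named list of overrides (unknown keys rejected).
#' @param path optional YAML file whose contents are applied as overrides
#'   (explicit `overrides` win).
#' @return nested configuration list of class `RunConfig`.
#' @export
run_config <- function(overrides = list(), path = NULL) {
  defaults <- list(
    paths = list(output = "cycifer_run"),
    phantom = phantom_config(),
    acquisition = unclass(acquisition_model()),
    prep = list(rolling_ball_radius = 50, shading = TRUE,
                unsharp = FALSE, unsharp_radius = 2, unsharp_amount = 0.5,
                max_theta_deg = 2, min_confidence = 0.2),
    segmentation = list(objective = "10X", min_sep = 5, min_area = 20L,
                        expansion_px = NULL),
    qc = list(n_bins = 100L, dr_percentiles = c(5, 95)),
    phenotyping = list(transform = "asinh", cofactor = 5,
                       p_low = 1, p_high = 99,
                       k_range = 2:6, restarts = 30L,
                       include_morphology = TRUE,
                       tsne = TRUE, perplexity = 30, tsne_max_cells = 500L),
    spatial = list(k = 4L, field_size = c(160, 160), n_sample = 1000L,
                   n_boot = 100L, gate_a = "PD1", gate_b = "PDL1",
                   stromal_marker = "aSMA", bandwidth = 50,
                   grid_spacing = 8, density_grid_spacing = 10,
                   hotspot_quantile = 0.9),
    seeds = list(phantom = 11L, render = 12L, phenotype = 13L,
                 tsne = 14L, entropy = 15L, bootstrap = 16L)
  )
  if (!is.null(path))
    defaults <- merge_config(defaults, yaml::read_yaml(path))
  cf <- merge_config(defaults, overrides)
  if (is.null(cf$segmentation$expansion_px))
    cf$segmentation$expansion_px <- expansion_pixels(cf$segmentation$objective)
  class(cf) <- c("RunConfig", "list")
  cf
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$paths <- NULL   # the hash identifies the analysis, not its location
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_json_sorted(cfg, tmp)
  unname(tools::md5sum(tmp))
}

hash_files <- function(files) {
  files <- files[file.exists(files)]
  h <- tools::md5sum(files)
  stats::setNames(as.vector(h), basename(files))
}

missing_input <- function(file, producer) {
  stop(errorCondition(
    sprintf("missing input %s: run the '%s' stage first", file, producer),
    class = c("cycifer_missing_input", "error", "condition")))
}

load_stack <- function(out, config) {
  tf <- file.path(out, "transforms.json")
  if (!file.exists(tf)) missing_input(tf, "prep")
  tj <- jsonlite::read_json(tf, simplifyVector = TRUE)
  acq <- do.call(acquisition_model, config$acquisition)
  mosaics <- lapply(seq_len(acq$n_cycles), function(cc)
    lapply(0:(acq$channels_per_cycle - 1), function(k) {
      f <- file.path(out, sprintf("mosaic_cyc%d_ch%d.tif", cc, k))
      if (!file.exists(f)) missing_input(f, "prep")
      read_tiff16(f) * 1.0
    }))
  transforms <- lapply(seq_len(nrow(tj)), function(i)
    rigid_transform(tj$dx[i], tj$dy[i], tj$theta[i]))
  assemble_stack(mosaics, transforms)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order. Every stage records
#' input/output file hashes in the run manifest, which is written (even on
#' failure) to `manifest.json` in the output directory; deterministic
#' stages reproduce identical hashes when re-run with the same
#' configuration and seeds.
#'
#' @param config a [run_config()].
#' @param stages subset of
#'   `c("simulate", "prep", "segment", "qc", "phenotype", "spatial")`.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "prep", "segment", "qc",
                                    "phenotype", "spatial")) {
  order_all <- c("simulate", "prep", "segment", "qc", "phenotype", "spatial")
  stages <- order_all[order_all %in% match.arg(stages, order_all,
                                               several.ok = TRUE)]
  out <- config$paths$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config),
                   version = as.character(utils::packageVersion("cycifer")),
                   stages = list())
  write_manifest <- function()
    write_json_sorted(manifest, file.path(out, "manifest.json"))
  on.exit(write_manifest())

  runners <- list(simulate = stage_simulate, prep = stage_prep,
                  segment = stage_segment, qc = stage_qc,
                  phenotype = stage_phenotype, spatial = stage_spatial)
  for (st in stages) {
    started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
    res <- tryCatch(
      withCallingHandlers(
        runners[[st]](out, config),
        warning = function(w) {
          manifest$stages[[st]]$warnings <<-
            c(manifest$stages[[st]]$warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[st]] <- c(manifest$stages[[st]],
                                 list(status = "failed",
                                      error = conditionMessage(res),
                                      started = started))
      write_manifest()
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", st, conditionMessage(res)),
        class = c("cycifer_stage_error", class(res))))
    }
    manifest$stages[[st]] <- c(manifest$stages[[st]],
      list(status = "ok", started = started,
           finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
           inputs = as.list(hash_files(res$inputs %||% character(0))),
           outputs = as.list(hash_files(res$outputs %||% character(0)))))
  }
  write_manifest()
  invisible(manifest)
}

stage_simulate <- function(out, config) {
  acq <- do.call(acquisition_model, config$acquisition)
  phantom <- generate_phantom(config$phantom, seed = config$seeds$phantom)
  tiles <- render_cycles(phantom, acq, seed = config$seeds$render)
  tdir <- file.path(out, "tiles")
  write_tile_set(tiles, tdir, phantom)
  list(outputs = list.files(tdir, full.names = TRUE))
}

stage_prep <- function(out, config) {
  tdir <- file.path(out, "tiles")
  if (!dir.exists(tdir)) missing_input(tdir, "simulate")
  ts <- read_tiles(tdir)
  acq <- do.call(acquisition_model, config$acquisition)
  lay <- tile_layout(acq)
  pr <- config$prep
  outputs <- character(0)

  shading <- list()
  for (k in sort(unique(ts$index$channel))) {
    if (pr$shading) {
      ch_tiles <- ts$tiles[ts$index$name[ts$index$channel == k]]
      shading[[k + 1]] <- estimate_shading(ch_tiles)
      f <- file.path(out, sprintf("shading_ch%d.tif", k))
      write_tiff16(shading[[k + 1]]$flatfield * 10000, f)
      outputs <- c(outputs, f)
    } else shading[k + 1] <- list(NULL)
  }

  mosaics <- list()
  for (cc in sort(unique(ts$index$cycle))) {
    mosaics[[cc]] <- list()
    for (k in sort(unique(ts$index$channel))) {
      sel <- ts$index[ts$index$cycle == cc & ts$index$channel == k, ]
      sel$ox <- sel$col * lay$stride[["x"]]; sel$oy <- sel$row * lay$stride[["y"]]
      tl <- lapply(ts$tiles[sel$name], function(t) {
        img <- t * 1.0
        if (!is.null(shading[[k + 1]])) img <- correct_tile(img, shading[[k + 1]])
        img <- subtract_background(img, pr$rolling_ball_radius)
        if (pr$unsharp) img <- unsharp_mask(img, pr$unsharp_radius,
                                            pr$unsharp_amount)
        img
      })
      st <- stitch_grid(tl, sel, lay$stride,
                        min_confidence = pr$min_confidence)
      for (wn in st$warnings) warning(wn)
      mosaics[[cc]][[k + 1]] <- st$mosaic
      f <- file.path(out, sprintf("mosaic_cyc%d_ch%d.tif", cc, k))
      write_tiff16(st$mosaic, f)
      outputs <- c(outputs, f)
    }
  }

  nuclear <- lapply(mosaics, `[[`, 1)
  transforms <- register_cycles(nuclear,
                                max_theta = pr$max_theta_deg * pi / 180,
                                min_confidence = pr$min_confidence)
  tj <- data.frame(cycle = seq_along(transforms),
                   dx = vapply(transforms, `[[`, 0, "dx"),
                   dy = vapply(transforms, `[[`, 0, "dy"),
                   theta = vapply(transforms, `[[`, 0, "theta"))
  f <- file.path(out, "transforms.json")
  write_json_sorted(tj, f)
  list(inputs = file.path(tdir, paste0(ts$index$name, ".tif")),
       outputs = c(outputs, f))
}

stage_segment <- function(out, config) {
  stack <- load_stack(out, config)
  sg <- config$segmentation
  H <- stack$dim[["height"]]; W <- stack$dim[["width"]]
  nuc_img <- matrix(stack$data[1, 1, , ], H, W)
  mask <- binarize_nuclei(nuc_img, min_area = sg$min_area)
  nuclei <- split_nuclei(mask, min_sep = sg$min_sep)
  comp <- expand_cytoplasm(nuclei, sg$expansion_px)
  ct <- quantify(list(nucleus = nuclei, cell = comp$cell,
                      cytoplasm = comp$cytoplasm), stack)
  f_ct <- file.path(out, "celltable.csv")
  write_celltable(ct, f_ct)
  f_nuc <- file.path(out, "nuclei_labels.tif")
  f_cell <- file.path(out, "cell_labels.tif")
  write_tiff16(nuclei, f_nuc); write_tiff16(comp$cell, f_cell)
  list(outputs = c(f_ct, f_nuc, f_cell))
}

stage_qc <- function(out, config) {
  f_ct <- file.path(out, "celltable.csv")
  if (!file.exists(f_ct)) missing_input(f_ct, "segment")
  ct <- read_celltable(f_ct)
  stack <- load_stack(out, config)
  sg <- config$segmentation
  H <- stack$dim[["height"]]; W <- stack$dim[["width"]]
  n_cyc <- stack$dim[["cycles"]]; n_chan <- stack$dim[["channels"]]

  # per-cycle nuclear segmentation for integrity analysis
  per_cycle <- lapply(seq_len(n_cyc), function(cc) {
    img <- matrix(stack$data[cc, 1, , ], H, W)
    img[!stack$valid[cc, , ]] <- 0
    lab <- split_nuclei(binarize_nuclei(img, min_area = sg$min_area),
                        min_sep = sg$min_sep)
    idx <- which(lab > 0)
    data.frame(cell_id = seq_len(max(0, max(lab))),
               centroid_x = as.numeric(rowsum((idx - 1) %/% H, lab[idx])) /
                 tabulate(lab[idx]),
               centroid_y = as.numeric(rowsum((idx - 1) %% H, lab[idx])) /
                 tabulate(lab[idx]),
               nucleus_area = tabulate(lab[idx]))
  })
  counts <- vapply(per_cycle, nrow, integer(1))
  integ <- integrity_curve(counts)
  retained <- vapply(seq_len(n_cyc), function(cc)
    if (cc == 1) 1 else match_nuclei(per_cycle[[1]], per_cycle[[cc]])$retained,
    numeric(1))

  drs <- list(); overlaps <- list()
  for (cc in seq_len(n_cyc)) for (k in seq_len(n_chan) - 1) {
    v <- ct[[sprintf("cyc%d_ch%d_cell_mean", cc, k)]]
    v <- v[is.finite(v) & v > 0]
    drs[[length(drs) + 1]] <- data.frame(
      cycle = cc, channel = k,
      dynamic_range = if (length(v) >= 20) dynamic_range(v) else NA_real_)
    if (cc > 1 && k == 0) {
      v1 <- ct$cyc1_ch0_cell_mean
      sc <- overlap_score(v1[is.finite(v1)], v, config$qc$n_bins)
      overlaps[[length(overlaps) + 1]] <- data.frame(
        cycle_a = 1, cycle_b = cc, channel = k, score = sc,
        class = classify_concordance(sc))
    }
  }
  rep <- qc_report(integrity = integ,
                   dynamic_ranges = do.call(rbind, drs),
                   overlaps = if (length(overlaps)) do.call(rbind, overlaps),
                   parameters = config$qc)
  f_json <- file.path(out, "qc_report.json")
  write_json_sorted(unclass(rep), f_json)
  f_csv <- file.path(out, "integrity.csv")
  utils::write.csv(data.frame(cycle = seq_len(n_cyc), count = counts,
                              normalized = integ, retained = retained),
                   f_csv, row.names = FALSE)
  list(inputs = f_ct, outputs = c(f_json, f_csv))
}

stage_phenotype <- function(out, config) {
  f_ct <- file.path(out, "celltable.csv")
  if (!file.exists(f_ct)) missing_input(f_ct, "segment")
  ct <- read_celltable(f_ct)
  ph <- config$phenotyping
  map <- marker_channel_map(config$phantom$markers,
                            config$acquisition$channels_per_cycle)
  map <- map[map$cycle <= config$acquisition$n_cycles, , drop = FALSE]
  feats <- transform_intensities(ct, map, method = ph$transform,
                                 cofactor = ph$cofactor)
  if (ph$include_morphology) {
    kept <- ct[ct$cell_id %in% as.integer(rownames(feats)), ]
    extra <- cbind(area = asinh(kept$cell_area / ph$cofactor),
                   hoechst = asinh(kept$cyc1_ch0_nuc_mean / ph$cofactor))
    feats <- cbind(feats, extra)
  }
  norm <- normalize_channels(feats, ph$p_low, ph$p_high)
  sel <- select_k(norm, ph$k_range, restarts = ph$restarts,
                  seed = config$seeds$phenotype)
  model <- sel$models[[as.character(sel$k)]]
  ct$cluster <- NA_integer_
  ct$cluster[match(as.integer(rownames(norm)), ct$cell_id)] <- model$assignment
  write_celltable(ct, f_ct)
  f_model <- file.path(out, "phenotype_model.json")
  write_json_sorted(list(k = model$k, weights = model$weights,
                         means = model$means,
                         covariances = lapply(seq_len(model$k), function(j)
                           model$covariances[, , j]),
                         nll = model$nll,
                         selection_curve = sel$curve), f_model)
  outputs <- c(f_ct, f_model)
  if (isTRUE(ph$tsne)) {
    n <- nrow(norm)
    take <- if (n > ph$tsne_max_cells)
      with_seed(config$seeds$tsne, sort(sample.int(n, ph$tsne_max_cells)))
    else seq_len(n)
    if (length(take) - 1 > 3 * ph$perplexity) {
      emb <- embed_tsne(norm[take, , drop = FALSE],
                        perplexity = ph$perplexity,
                        seed = config$seeds$tsne)
      f_emb <- file.path(out, "tsne.csv")
      utils::write.csv(data.frame(cell_id = rownames(emb),
                                  tsne1 = emb[, 1], tsne2 = emb[, 2]),
                       f_emb, row.names = FALSE)
      outputs <- c(outputs, f_emb)
    } else warning("too few cells for t-SNE; embedding skipped")
  }
  list(inputs = f_ct, outputs = outputs)
}

stage_spatial <- function(out, config) {
  f_ct <- file.path(out, "celltable.csv")
  if (!file.exists(f_ct)) missing_input(f_ct, "segment")
  ct <- read_celltable(f_ct)
  sp <- config$spatial
  map <- marker_channel_map(config$phantom$markers,
                            config$acquisition$channels_per_cycle)
  map <- map[map$cycle <= config$acquisition$n_cycles, , drop = FALSE]
  ctv <- ct[ct$valid & stats::complete.cases(marker_matrix(ct, map)), ]
  mm <- marker_matrix(ctv, map)
  W <- config$phantom$canvas[1]; H <- config$phantom$canvas[2]

  reg <- assign_regions(ctv, mm[, sp$stromal_marker],
                        bandwidth = sp$bandwidth,
                        grid_spacing = sp$grid_spacing,
                        width = W, height = H)
  ct$region_label <- NA_character_
  ct$region_label[match(ctv$cell_id, ct$cell_id)] <- reg$region
  write_celltable(ct, f_ct)

  gates <- list(gate_positive(mm[, sp$gate_a]),
                gate_positive(mm[, sp$gate_b]))
  names(gates) <- c(sp$gate_a, sp$gate_b)
  outputs <- f_ct

  grid <- make_grid(W, H, sp$density_grid_spacing)
  pts_a <- cbind(ctv$centroid_x, ctv$centroid_y)[gates[[1]], , drop = FALSE]
  pts_b <- cbind(ctv$centroid_x, ctv$centroid_y)[gates[[2]], , drop = FALSE]
  if (nrow(pts_a) >= sp$k && nrow(pts_b) >= sp$k) {
    da <- knn_density(pts_a, grid, k = sp$k)
    db <- knn_density(pts_b, grid, k = sp$k)
    gi <- pmin(pmax(floor(grid$y / sp$grid_spacing) + 1, 1), nrow(reg$mask))
    gj <- pmin(pmax(floor(grid$x / sp$grid_spacing) + 1, 1), ncol(reg$mask))
    co <- cooccurrence_map(da, db, reg$mask[cbind(gi, gj)],
                           hotspot_quantile = sp$hotspot_quantile)
    f_co <- file.path(out, "cooccurrence.csv")
    utils::write.csv(cbind(co$map, hotspot = co$hotspots), f_co,
                     row.names = FALSE)
    write_json_sorted(list(region_means = as.list(co$region_means),
                           fold_tumor_vs_stroma = co$fold),
                      file.path(out, "cooccurrence_summary.json"))
    outputs <- c(outputs, f_co, file.path(out, "cooccurrence_summary.json"))
  } else warning("too few gate-positive cells for kNN density maps")

  counts <- bootstrap_counts(gates, ct$region_label[match(ctv$cell_id, ct$cell_id)],
                             n_boot = sp$n_boot, seed = config$seeds$bootstrap)
  f_counts <- file.path(out, "bootstrap_counts.csv")
  utils::write.csv(counts, f_counts, row.names = FALSE)
  outputs <- c(outputs, f_counts)

  fields <- grid_fields(ctv, sp$field_size[1], sp$field_size[2])
  if (nrow(ctv) > sp$n_sample) {
    em <- lapply(colnames(mm), function(mk)
      cbind(marker = mk, entropy_map(ctv, mm[, mk], fields,
                                     n_sample = sp$n_sample,
                                     seed = config$seeds$entropy)))
    em <- do.call(rbind, em)
    f_ent <- file.path(out, "entropy_map.csv")
    utils::write.csv(em, f_ent, row.names = FALSE)
    outputs <- c(outputs, f_ent)
  } else warning("too few cells for the entropy map (needs > n_sample)")
  list(inputs = f_ct, outputs = outputs)
}
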