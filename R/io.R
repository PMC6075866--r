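# Standard-format I/O: 16-bit grayscale TIFF tiles and mosaics, CSV cell
# tables, JSON reports with sorted keys (stable hashes across runs).

tile_name_pattern <- "^cyc(\\d+)_ch(\\d+)_r(\\d+)_c(\\d+)\\.tif$"

#' Write an image as single-plane 16-bit grayscale TIFF
#'
#' Values are rounded and clipped to the 0..65535 count range (label images
#' with fewer than 2^16 labels round-trip exactly).
#'
#' @param img numeric or integer matrix.
#' @param path output file.
#' @export
write_tiff16 <- function(img, path) {
  img <- pmin(pmax(round(img), 0), 65535)
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a single-plane TIFF as an integer count matrix
#' @param path file written by [write_tiff16()] or equivalent.
#' @export
read_tiff16 <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

# Recursively sort list names so serialized JSON is byte-stable.
sort_keys <- function(x) {
  if (is.data.frame(x)) return(x)   # column order is already deterministic
  if (is.list(x) && !is.null(names(x)) && length(x))
    x <- lapply(x[order(names(x))], sort_keys)
  else if (is.list(x)) x <- lapply(x, sort_keys)
  x
}

#' Write JSON with sorted keys and full float precision
#' @param x list to serialize.
#' @param path output file.
#' @export
write_json_sorted <- function(x, path) {
  jsonlite::write_json(sort_keys(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a rendered tile set (and ground truth) to a directory
#'
#' Tiles are written as `cyc{cc}_ch{k}_r{row}_c{col}.tif`; the truth
#' manifest (applied per-cycle rigid transforms, autofluorescence schedule,
#' tile layout, seed) as `truth_manifest.json`; and, when the phantom is
#' supplied, the ground-truth cell table as `ground_truth.csv` with one
#' `expr_<marker>` column per marker.
#'
#' @param tileset a [render_cycles()] result.
#' @param dir output directory (created if needed).
#' @param phantom optional [generate_phantom()] result.
#' @return `dir`, invisibly.
#' @export
write_tile_set <- function(tileset, dir, phantom = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tileset$tiles))
    write_tiff16(tileset$tiles[[nm]], file.path(dir, paste0(nm, ".tif")))
  man <- tileset$manifest
  lay <- man$layout
  write_json_sorted(list(
    transforms = man$transforms,
    autofluorescence = man$autofluorescence,
    seed = man$seed,
    expression_scale = man$expression_scale,
    layout = list(origins = lay$origins, stride = as.list(lay$stride),
                  mosaic = as.list(lay$mosaic))),
    file.path(dir, "truth_manifest.json"))
  if (!is.null(phantom)) {
    gt <- phantom$cells
    expr <- phantom$expression
    colnames(expr) <- paste0("expr_", colnames(expr))
    utils::write.csv(cbind(gt, expr), file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read an indexed tile collection from a directory
#'
#' Tiles are indexed by (cycle, channel, row, col) parsed from the file
#' names. All tiles must share one shape; gaps relative to the full
#' cycle x channel x grid cross-product are reported in the `gaps`
#' attribute and as a warning.
#'
#' @param dir directory containing tiles.
#' @param pattern filename regex with cycle/channel/row/col capture groups.
#' @return list with `tiles` (named list of integer matrices) and `index`
#'   (data.frame name/cycle/channel/row/col), class `RawTileSet`.
#' @export
read_tiles <- function(dir, pattern = tile_name_pattern) {
  files <- list.files(dir, pattern = pattern)
  if (!length(files))
    stop("no tiles matching pattern found in ", dir)
  m <- regmatches(files, regexec(pattern, files))
  idx <- data.frame(
    name = sub("\\.tif$", "", files),
    cycle = as.integer(vapply(m, `[`, "", 2)),
    channel = as.integer(vapply(m, `[`, "", 3)),
    row = as.integer(vapply(m, `[`, "", 4)),
    col = as.integer(vapply(m, `[`, "", 5)),
    stringsAsFactors = FALSE)
  tiles <- lapply(file.path(dir, files), read_tiff16)
  names(tiles) <- idx$name
  shapes <- vapply(tiles, function(t) paste(dim(t), collapse = "x"), "")
  if (length(unique(shapes)) > 1L)
    stop("tiles have mixed shapes: ", paste(unique(shapes), collapse = ", "))
  expected <- expand.grid(cycle = sort(unique(idx$cycle)),
                          channel = sort(unique(idx$channel)),
                          row = sort(unique(idx$row)),
                          col = sort(unique(idx$col)))
  have <- paste(idx$cycle, idx$channel, idx$row, idx$col)
  gaps <- expected[!(paste(expected$cycle, expected$channel,
                           expected$row, expected$col) %in% have), ]
  if (nrow(gaps))
    warning("tile grid has ", nrow(gaps), " gap(s); see attr(, 'gaps')")
  out <- structure(list(tiles = tiles, index = idx), class = "RawTileSet")
  attr(out, "gaps") <- gaps
  out
}

#' Write a cell table as CSV with a fixed column order
#' @param celltable data.frame from [quantify()].
#' @param path output file.
#' @export
write_celltable <- function(celltable, path) {
  out <- celltable
  for (j in seq_along(out))   # full double precision survives the round-trip
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA, sprintf("%.17g", out[[j]]))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table written by [write_celltable()]
#' @param path CSV file.
#' @export
read_celltable <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
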