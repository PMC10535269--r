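#' Lightweight georeferenced grid containers
#'
#' All rasters in this package share one convention: a regular grid with
#' square pixels, pixel-centre coordinates, row 1 at the northern edge and
#' column 1 at the western edge. A single-band grid is a numeric matrix plus
#' origin and resolution; a stack is a named list of aligned matrices.
#'
#' @param values numeric matrix (rows = north to south).
#' @param res pixel size in metres (or km for coarse climate grids).
#' @param xmin x coordinate of the western grid edge.
#' @param ymax y coordinate of the northern grid edge.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, res = 16, xmin = 0, ymax = nrow(values) * res) {
  stopifnot(is.matrix(values), nrow(values) > 0, ncol(values) > 0, res > 0)
  structure(list(values = values, res = res, xmin = xmin, ymax = ymax),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d px, res %g, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$res, x$xmin, x$ymax))
  invisible(x)
}

#' Multi-band stack of aligned grids
#'
#' @param layers named list of numeric matrices with identical dimensions.
#' @inheritParams grid_raster
#' @return an object of class `grid_stack`.
#' @export
grid_stack <- function(layers, res = 16, xmin = 0,
                       ymax = nrow(layers[[1]]) * res) {
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)))
  d <- dim(layers[[1]])
  for (nm in names(layers)) {
    stopifnot(is.matrix(layers[[nm]]), identical(dim(layers[[nm]]), d))
  }
  structure(list(layers = layers, res = res, xmin = xmin, ymax = ymax),
            class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("<grid_stack> %d layers (%s), %d x %d px, res %g\n",
              length(x$layers), paste(names(x$layers), collapse = ","),
              nrow(x$layers[[1]]), ncol(x$layers[[1]]), x$res))
  invisible(x)
}

grid_dim <- function(g) {
  if (inherits(g, "grid_stack")) dim(g$layers[[1]]) else dim(g$values)
}

#' Pixel-centre coordinates of every cell
#'
#' @param g a `grid_raster` or `grid_stack`.
#' @return data.frame with columns `row`, `col`, `x`, `y` in row-major order.
#' @export
grid_coords <- function(g) {
  d <- grid_dim(g)
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  data.frame(row = rc$row, col = rc$col,
             x = g$xmin + (rc$col - 0.5) * g$res,
             y = g$ymax - (rc$row - 0.5) * g$res)
}

#' Map x/y coordinates to row/col indices
#'
#' Points outside the grid get NA indices.
#' @param g grid object.
#' @param x,y point coordinates.
#' @return data.frame with columns `row`, `col`.
#' @export
grid_cell_at <- function(g, x, y) {
  d <- grid_dim(g)
  col <- floor((x - g$xmin) / g$res) + 1L
  row <- floor((g$ymax - y) / g$res) + 1L
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract stack values at points (nearest pixel, no interpolation)
#'
#' @param g a `grid_stack`.
#' @param x,y point coordinates.
#' @return matrix with one row per point, one column per layer.
#' @export
grid_extract <- function(g, x, y) {
  stopifnot(inherits(g, "grid_stack"))
  rc <- grid_cell_at(g, x, y)
  d <- grid_dim(g)
  out <- matrix(NA_real_, nrow = length(x), ncol = length(g$layers),
                dimnames = list(NULL, names(g$layers)))
  ok <- !is.na(rc$row)
  idx <- cbind(rc$row[ok], rc$col[ok])
  for (j in seq_along(g$layers)) out[ok, j] <- g$layers[[j]][idx]
  out
}

#' Write a grid to disk as ESRI ASCII raster(s)
#'
#' Single-band grids become one `.asc` file. Stacks become one `.asc` per
#' layer (`<prefix>_<layer>.asc`) plus a `<prefix>.json` sidecar listing the
#' layers and grid metadata. The `.asc` header carries the georeferencing
#' (lower-left corner, cell size, nodata sentinel); values are written at
#' full double precision.
#'
#' @param g grid object.
#' @param path output path: an `.asc` file for a `grid_raster`, a prefix
#'   (no extension) for a `grid_stack`.
#' @return `path`, invisibly.
#' @export
write_grid <- function(g, path) {
  if (inherits(g, "grid_stack")) {
    files <- character(0)
    for (nm in names(g$layers)) {
      f <- paste0(path, "_", nm, ".asc")
      write_asc(g$layers[[nm]], f, g$res, g$xmin, g$ymax)
      files <- c(files, basename(f))
    }
    meta <- list(res = g$res, xmin = g$xmin, ymax = g$ymax,
                 layers = names(g$layers), files = files,
                 convention = "pixel-centre coordinates, row 1 = north")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    write_asc(g$values, path, g$res, g$xmin, g$ymax)
  }
  invisible(path)
}

write_asc <- function(m, path, res, xmin, ymax, nodata = -9999) {
  vals <- m
  vals[is.na(vals)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %.10g", xmin),
               sprintf("yllcorner %.10g", ymax - nrow(m) * res),
               sprintf("cellsize %.10g", res),
               sprintf("NODATA_value %d", nodata)), con)
  utils::write.table(format(vals, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  h <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                       tolower(vapply(kv, `[`, "", 1)))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == h[["nodata_value"]]] <- NA_real_
  grid_raster(m, res = h[["cellsize"]], xmin = h[["xllcorner"]],
              ymax = h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]])
}

#' Read a grid written by [write_grid()]
#'
#' @param path an `.asc` file (single grid) or a stack prefix whose
#'   `<prefix>.json` sidecar exists.
#' @return a `grid_raster` or `grid_stack`.
#' @export
read_grid <- function(path) {
  if (grepl("\\.asc$", path)) return(read_asc(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  layers <- lapply(file.path(dirname(path), meta$files),
                   function(f) read_asc(f)$values)
  names(layers) <- meta$layers
  grid_stack(layers, res = meta$res, xmin = meta$xmin, ymax = meta$ymax)
}
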