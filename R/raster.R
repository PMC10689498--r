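# Lightweight multi-layer raster grid on a planar 1-km-style lattice.
# Layers are plain matrices; row i maps to y = ymin + (i - 0.5) * cellsize
# (row 1 is the southern edge) and column j to x = xmin + (j - 0.5) * cellsize.
# Cell membership uses the half-open convention [x, x + cellsize).

#' Create a raster stack
#'
#' Bundles named, equally-dimensioned matrix layers with a shared planar
#' georeference (origin and square cell size). This is the container used for
#' climate and landcover variables throughout the package.
#'
#' @param layers Named list of numeric matrices with identical dimensions.
#' @param xmin,ymin Coordinates of the lower-left corner (km).
#' @param cellsize Cell edge length (km).
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(layers, xmin = 0, ymin = 0, cellsize = 1) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("`layers` must be a non-empty named list of matrices")
  if (is.null(names(layers)) || any(!nzchar(names(layers))) ||
      anyDuplicated(names(layers)))
    stop("layers must have unique non-empty names")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share the same dimensions")
  stop_if_not_number(cellsize, "cellsize", positive = TRUE)
  structure(
    list(layers = lapply(layers, function(m) {
      storage.mode(m) <- "double"
      m
    }),
    xmin = xmin, ymin = ymin, cellsize = cellsize,
    nrow = dims[1, 1], ncol = dims[2, 1]),
    class = "raster_stack"
  )
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d x %d cells (%.3g km), %d layer(s)\n",
              x$nrow, x$ncol, x$cellsize, length(x$layers)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + x$ncol * x$cellsize,
              x$ymin, x$ymin + x$nrow * x$cellsize))
  invisible(x)
}

#' @export
dim.raster_stack <- function(x) c(x$nrow, x$ncol, length(x$layers))

#' @export
names.raster_stack <- function(x) names(x$layers)

n_cells <- function(rs) rs$nrow * rs$ncol

# Cell centre coordinates in matrix (column-major) cell order.
rs_xy <- function(rs) {
  i <- rep.int(seq_len(rs$nrow), rs$ncol)
  j <- rep(seq_len(rs$ncol), each = rs$nrow)
  cbind(x = rs$xmin + (j - 0.5) * rs$cellsize,
        y = rs$ymin + (i - 0.5) * rs$cellsize)
}

#' Extract layer values as a cells-by-layers matrix
#'
#' @param rs A [raster_stack()].
#' @param layers Layer names (default all).
#' @return Numeric matrix, one row per cell in matrix (column-major) order.
#' @export
rs_values <- function(rs, layers = NULL) {
  layers <- layers %||% names(rs$layers)
  missing <- setdiff(layers, names(rs$layers))
  if (length(missing))
    stop("unknown layer(s): ", paste(missing, collapse = ", "))
  out <- vapply(layers, function(nm) as.vector(rs$layers[[nm]]),
                numeric(n_cells(rs)))
  matrix(out, ncol = length(layers), dimnames = list(NULL, layers))
}

#' Map point coordinates to cell indices
#'
#' @param rs A [raster_stack()].
#' @param xy Two-column matrix or data frame of x/y coordinates.
#' @return Integer vector of (column-major) cell indices; `NA` outside the
#'   grid. Membership is half-open: a point on a cell's lower/left edge
#'   belongs to that cell.
#' @export
rs_cell <- function(rs, xy) {
  xy <- as.matrix(xy[, 1:2, drop = FALSE])
  j <- floor((xy[, 1] - rs$xmin) / rs$cellsize) + 1
  i <- floor((xy[, 2] - rs$ymin) / rs$cellsize) + 1
  ok <- i >= 1 & i <= rs$nrow & j >= 1 & j <= rs$ncol
  out <- rep(NA_integer_, nrow(xy))
  out[ok] <- as.integer((j[ok] - 1) * rs$nrow + i[ok])
  out
}

# Coordinates of cell centres for given cell indices.
rs_cell_xy <- function(rs, cells) {
  i <- (cells - 1L) %% rs$nrow + 1L
  j <- (cells - 1L) %/% rs$nrow + 1L
  cbind(x = rs$xmin + (j - 0.5) * rs$cellsize,
        y = rs$ymin + (i - 0.5) * rs$cellsize)
}

#' Extract environment values at point locations
#'
#' @inheritParams rs_values
#' @param xy Two-column matrix/data frame of coordinates.
#' @return Matrix of layer values at the cells containing each point.
#' @export
rs_extract <- function(rs, xy, layers = NULL) {
  cells <- rs_cell(rs, xy)
  if (anyNA(cells)) stop("some points fall outside the raster extent")
  rs_values(rs, layers)[cells, , drop = FALSE]
}

# Build a single-layer stack from a vector of per-cell values (matrix order).
rs_from_values <- function(rs, values, name = "value") {
  m <- matrix(values, nrow = rs$nrow, ncol = rs$ncol)
  raster_stack(stats::setNames(list(m), name),
               xmin = rs$xmin, ymin = rs$ymin, cellsize = rs$cellsize)
}

#' Define a rectangular study area
#'
#' @param name Area label.
#' @param xmin,xmax,ymin,ymax Extent (km).
#' @return An object of class `study_area`.
#' @export
study_area <- function(name, xmin, xmax, ymin, ymax) {
  if (!(xmax > xmin && ymax > ymin)) stop("study area extent is empty")
  structure(list(name = name, xmin = xmin, xmax = xmax,
                 ymin = ymin, ymax = ymax),
            class = "study_area")
}

#' @export
print.study_area <- function(x, ...) {
  cat(sprintf("<study_area> %s: x [%g, %g], y [%g, %g] (%g km2)\n", x$name,
              x$xmin, x$xmax, x$ymin, x$ymax,
              (x$xmax - x$xmin) * (x$ymax - x$ymin)))
  invisible(x)
}

#' Test whether points fall inside a study area
#'
#' Half-open on the upper edges so nested tilings do not double-count.
#'
#' @param area A [study_area()].
#' @param xy Two-column matrix/data frame of coordinates.
#' @return Logical vector.
#' @export
area_contains <- function(area, xy) {
  xy <- as.matrix(xy[, 1:2, drop = FALSE])
  xy[, 1] >= area$xmin & xy[, 1] < area$xmax &
    xy[, 2] >= area$ymin & xy[, 2] < area$ymax
}

#' Cell indices of a raster inside a study area
#'
#' @param rs A [raster_stack()].
#' @param area A [study_area()] or `NULL` for all cells.
#' @return Integer cell indices (cells whose centres fall inside).
#' @export
rs_area_cells <- function(rs, area = NULL) {
  if (is.null(area)) return(seq_len(n_cells(rs)))
  which(area_contains(area, rs_xy(rs)))
}

#' Crop a raster stack to a study area
#'
#' @inheritParams rs_area_cells
#' @return A smaller [raster_stack()] covering the cells whose centres fall
#'   inside `area`.
#' @export
rs_crop <- function(rs, area) {
  xy <- rs_xy(rs)
  keep <- area_contains(area, xy)
  if (!any(keep)) stop("study area contains no cells")
  cells <- which(keep)
  i <- (cells - 1L) %% rs$nrow + 1L
  j <- (cells - 1L) %/% rs$nrow + 1L
  ri <- range(i); rj <- range(j)
  layers <- lapply(rs$layers, function(m) m[ri[1]:ri[2], rj[1]:rj[2], drop = FALSE])
  raster_stack(layers,
               xmin = rs$xmin + (rj[1] - 1) * rs$cellsize,
               ymin = rs$ymin + (ri[1] - 1) * rs$cellsize,
               cellsize = rs$cellsize)
}

#' Write one layer as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS software.
#'
#' @param rs A [raster_stack()].
#' @param layer Layer name.
#' @param file Output path.
#' @param nodata Value written for `NA` cells.
#' @export
write_esri_ascii <- function(rs, layer, file, nodata = -9999) {
  m <- rs$layers[[layer]]
  if (is.null(m)) stop("unknown layer: ", layer)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", rs$ncol),
    sprintf("nrows %d", rs$nrow),
    sprintf("xllcorner %.10g", rs$xmin),
    sprintf("yllcorner %.10g", rs$ymin),
    sprintf("cellsize %.10g", rs$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  m[is.na(m)] <- nodata
  # rows written north to south
  for (i in rev(seq_len(rs$nrow)))
    writeLines(paste(format(m[i, ], trim = TRUE, digits = 10), collapse = " "),
               con)
  invisible(file)
}

#' Read an ESRI ASCII grid
#'
#' @param file Path to an ASCII grid.
#' @param name Layer name for the result.
#' @return A single-layer [raster_stack()].
#' @export
read_esri_ascii <- function(file, name = "value") {
  lines <- readLines(file)
  hdr <- list()
  nhdr <- 0
  for (ln in lines[1:6]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1
    } else break
  }
  vals <- scan(text = paste(lines[-seq_len(nhdr)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # back to south-up storage
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_stack(stats::setNames(list(m), name),
               xmin = hdr$xllcorner, ymin = hdr$yllcorner,
               cellsize = hdr$cellsize)
}
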