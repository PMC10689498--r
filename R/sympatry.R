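# Sympatry mapping: fuzzy intersection of two species' probability maps and
# co-occurrence profiles along a transect set orthogonally to the contact.

#' Fuzzy intersection of two probability rasters
#'
#' Per-cell fuzzy AND of two occurrence-probability maps, giving a
#' continuous co-occurrence (sympatry) raster.
#'
#' @param a,b Single-layer [raster_stack()]s on the same grid with values
#'   in `[0, 1]` (`NA` allowed; the result is `NA` where either input is).
#' @param method `"min"` (default, standard fuzzy intersection) or
#'   `"product"`.
#' @return Single-layer [raster_stack()] named `cooccurrence`.
#' @export
fuzzy_intersection <- function(a, b, method = c("min", "product")) {
  method <- match.arg(method)
  ma <- a$layers[[1]]; mb <- b$layers[[1]]
  if (!identical(dim(ma), dim(mb)) || a$cellsize != b$cellsize ||
      a$xmin != b$xmin || a$ymin != b$ymin)
    stop("rasters are not on the same grid")
  rng <- range(c(ma, mb), na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("raster values must lie in [0, 1]")
  m <- if (method == "min") pmin(ma, mb) else ma * mb
  raster_stack(list(cooccurrence = m), xmin = a$xmin, ymin = a$ymin,
               cellsize = a$cellsize)
}

#' Define a transect
#'
#' @param p1,p2 Numeric length-2 endpoints (x, y), distinct.
#' @return Object of class `transect` with endpoints, `length` and unit
#'   direction.
#' @export
transect <- function(p1, p2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  L <- sqrt(sum((p2 - p1)^2))
  if (!is.finite(L) || L <= 0) stop("transect endpoints must be distinct")
  structure(list(p1 = p1, p2 = p2, length = L, u = (p2 - p1) / L),
            class = "transect")
}

#' @export
print.transect <- function(x, ...) {
  cat(sprintf("<transect> (%.2f, %.2f) -> (%.2f, %.2f), length %.2f km\n",
              x$p1[1], x$p1[2], x$p2[1], x$p2[2], x$length))
  invisible(x)
}

#' Place a transect orthogonally to the contact
#'
#' Cells above the co-occurrence quantile define the sympatric band; its
#' first principal axis is the average direction of the contact, and the
#' transect runs through the band's centroid along the second (orthogonal)
#' axis, extended to the raster extent. A near-isotropic band triggers a
#' warning and a tie-break towards the grid x-axis.
#'
#' @param r Single-layer co-occurrence [raster_stack()].
#' @param quantile Quantile defining the high-co-occurrence band (default
#'   0.9); at least 3 cells must exceed it.
#' @return A [transect()].
#' @export
auto_transect <- function(r, quantile = 0.9) {
  v <- as.vector(r$layers[[1]])
  ok <- !is.na(v)
  th <- stats::quantile(v[ok], quantile, names = FALSE)
  high <- which(ok & v >= th)
  if (length(high) < 3)
    stop("fewer than 3 cells above the co-occurrence quantile")
  xy <- rs_cell_xy(r, high)
  ctr <- colMeans(xy)
  pc <- stats::prcomp(xy, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] <= 0 || pc$sdev[2] / pc$sdev[1] > 0.95) {
    warning("high-co-occurrence cells are nearly isotropic; ",
            "transect direction defaults to the grid x-axis")
    dir <- c(1, 0)
  } else {
    dir <- pc$rotation[, 2]
  }
  # extend from the centroid to the raster extent along +-dir
  xr <- c(r$xmin, r$xmin + r$ncol * r$cellsize)
  yr <- c(r$ymin, r$ymin + r$nrow * r$cellsize)
  tmax <- Inf; tmin <- -Inf
  for (axis in 1:2) {
    rng <- if (axis == 1) xr else yr
    if (abs(dir[axis]) > 1e-12) {
      tt <- (rng - ctr[axis]) / dir[axis]
      tmin <- max(tmin, min(tt))
      tmax <- min(tmax, max(tt))
    }
  }
  transect(ctr + tmin * dir, ctr + tmax * dir)
}

#' Project a co-occurrence raster onto a transect
#'
#' Every non-missing cell centre is orthogonally projected onto the
#' transect line; cells whose foot falls outside the segment are excluded.
#' The result is sorted by distance along the transect.
#'
#' @param r Single-layer co-occurrence [raster_stack()].
#' @param tr A [transect()].
#' @return Data frame of class `sympatry_profile` with columns
#'   `distance_km`, `offset_km` (signed perpendicular offset) and
#'   `p_cooccurrence`, plus attributes `peak` (max probability),
#'   `peak_distance` and `flatness` (max - min).
#' @export
transect_profile <- function(r, tr) {
  v <- as.vector(r$layers[[1]])
  ok <- which(!is.na(v))
  if (!length(ok)) stop("raster has no non-missing cells")
  xy <- rs_cell_xy(r, ok)
  rel <- sweep(xy, 2, tr$p1, "-")
  t <- rel[, 1] * tr$u[1] + rel[, 2] * tr$u[2]
  off <- rel[, 1] * tr$u[2] - rel[, 2] * tr$u[1]
  keep <- t >= 0 & t <= tr$length
  if (!any(keep)) stop("no cells project onto the transect segment")
  o <- order(t[keep])
  out <- data.frame(distance_km = t[keep][o], offset_km = off[keep][o],
                    p_cooccurrence = v[ok][keep][o])
  attr(out, "peak") <- max(out$p_cooccurrence)
  attr(out, "peak_distance") <- out$distance_km[which.max(out$p_cooccurrence)]
  attr(out, "flatness") <- diff(range(out$p_cooccurrence))
  class(out) <- c("sympatry_profile", "data.frame")
  out
}

#' @export
print.sympatry_profile <- function(x, ...) {
  cat(sprintf(
    "<sympatry_profile> %d cells | peak %.3f at %.1f km | range %.3f\n",
    nrow(x), attr(x, "peak"), attr(x, "peak_distance"), attr(x, "flatness")))
  invisible(x)
}

#' Write a sympatry profile as CSV
#'
#' Columns `distance_km,offset_km,p_cooccurrence`.
#'
#' @param profile A [transect_profile()] result.
#' @param file Output path.
#' @export
write_profile <- function(profile, file) {
  utils::write.csv(as.data.frame(profile), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' Write transect endpoints as a GeoJSON LineString
#'
#' @param tr A [transect()].
#' @param file Output path.
#' @export
write_transect_geojson <- function(tr, file) {
  obj <- list(type = "Feature",
              geometry = list(type = "LineString",
                              coordinates = list(tr$p1, tr$p2)),
              properties = list(length_km = tr$length))
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}
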