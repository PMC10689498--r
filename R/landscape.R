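# Synthetic landscape and occurrence generator.
#
# Emulates the study design the package targets: one large area holding
# three small contact zones at different latitudes, nine climate-like layers
# (smooth random fields plus a north-south gradient and optional per-zone
# offsets) and four landcover-fraction layers (softmax of latent smooth
# fields). A per-zone disturbance scalar mixes landcover convexly towards a
# dominant agriculture class, homogenising habitat. Species occurrences are
# sampled from Gaussian niche truths so downstream estimators can be tested
# against known answers.

#' Configure a synthetic landscape
#'
#' @param nrow,ncol Grid dimensions (cells).
#' @param cellsize Cell edge (km); default 1 km, the resolution of the
#'   occurrence data the generator emulates.
#' @param n_climate,n_landcover Numbers of climate and landcover layers.
#' @param autocorr Spatial autocorrelation length of the smooth fields
#'   (cells; Gaussian smoothing kernel sd).
#' @param noise_sd Marginal sd of the smooth stochastic component of each
#'   climate layer (environment units).
#' @param gradient North-south slope per climate layer (units per km),
#'   recycled to `n_climate`. Defaults to a gradient on the first two layers
#'   (a temperature-like and a precipitation-like axis) and none elsewhere.
#' @param climate_cor Optional target inter-layer correlation matrix for the
#'   stochastic components (symmetric, unit diagonal, positive semi-definite).
#' @param zones Optional list of zone specs, each a list with elements
#'   `area` (a [study_area()]), `climate_offset` (scalar or per-layer vector,
#'   environment units) and `disturbance` (scalar in `[0,1]`).
#' @param seed Integer seed; the whole stack is reproducible from it.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(nrow = 190, ncol = 190, cellsize = 1,
                             n_climate = 9, n_landcover = 4,
                             autocorr = 8, noise_sd = 1,
                             gradient = NULL, climate_cor = NULL,
                             zones = list(), seed = 1) {
  stop_if_not_number(nrow, "nrow", positive = TRUE)
  stop_if_not_number(ncol, "ncol", positive = TRUE)
  stop_if_not_number(cellsize, "cellsize", positive = TRUE)
  stop_if_not_number(autocorr, "autocorr", positive = TRUE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  gradient <- gradient %||% c(0.02, -0.015, rep(0, max(0, n_climate - 2)))
  gradient <- rep_len(gradient, n_climate)
  if (!is.null(climate_cor)) {
    climate_cor <- as.matrix(climate_cor)
    if (nrow(climate_cor) != n_climate || ncol(climate_cor) != n_climate)
      stop("`climate_cor` must be n_climate x n_climate")
    if (max(abs(climate_cor - t(climate_cor))) > 1e-8)
      stop("`climate_cor` must be symmetric")
    if (max(abs(diag(climate_cor) - 1)) > 1e-8)
      stop("`climate_cor` must have unit diagonal")
    ev <- eigen(climate_cor, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("`climate_cor` is not positive semi-definite")
  }
  for (z in zones) {
    if (!inherits(z$area, "study_area"))
      stop("each zone needs a `study_area` in $area")
    d <- z$disturbance %||% 0
    if (d < 0 || d > 1) stop("zone disturbance must lie in [0, 1]")
  }
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cellsize = cellsize, n_climate = as.integer(n_climate),
                 n_landcover = as.integer(n_landcover), autocorr = autocorr,
                 noise_sd = noise_sd, gradient = gradient,
                 climate_cor = climate_cor, zones = zones,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

# Smooth unit-variance Gaussian random field: white noise convolved with a
# separable Gaussian kernel; padding avoids edge variance loss, and the
# kernel is normalised so the output keeps (approximately) unit variance.
smooth_field <- function(nr, nc, range_cells) {
  m <- ceiling(3 * range_cells)
  k <- stats::dnorm(seq(-m, m), sd = range_cells)
  k <- k / sqrt(sum(k^2))
  z <- matrix(stats::rnorm((nr + 2 * m) * (nc + 2 * m)),
              nrow = nr + 2 * m)
  z <- apply(z, 2, function(v) stats::filter(v, k, sides = 2))
  z <- t(apply(z, 1, function(v) stats::filter(v, k, sides = 2)))
  z[(m + 1):(m + nr), (m + 1):(m + nc)]
}

default_landcover_names <- function(n) {
  base <- c("agriculture", "forest", "shrub", "grassland")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("lc", seq_len(n - length(base)) + length(base)))
}

#' Generate the synthetic environmental raster stack
#'
#' Climate layers are smooth random fields (optionally correlated across
#' layers via a Cholesky mix), scaled by `noise_sd`, plus a north-south
#' linear gradient and per-zone additive offsets. Landcover layers are
#' per-cell fractions in `[0,1]` summing to at most 1 (softmax over latent
#' smooth fields plus a residual "other" class). Zone disturbance `d` mixes
#' each cell's fractions convexly towards a dominant agriculture profile,
#' which monotonically raises the agriculture fraction and lowers the
#' Shannon evenness of the composition.
#'
#' @param config A [landscape_config()].
#' @return A [raster_stack()] with `n_climate` layers named `clim1...` and
#'   `n_landcover` landcover layers. Identical config (including seed) gives
#'   a bit-identical stack.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$nrow; nc <- config$ncol
  with_seed(config$seed, {
    ncl <- config$n_climate
    fields <- matrix(0, nr * nc, ncl)
    for (l in seq_len(ncl)) fields[, l] <- as.vector(smooth_field(nr, nc, config$autocorr))
    if (!is.null(config$climate_cor)) {
      # eigen-based square root tolerates semi-definite targets
      e <- eigen(config$climate_cor, symmetric = TRUE)
      rt <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), ncl) %*% t(e$vectors)
      fields <- fields %*% rt
    }
    xy <- {
      i <- rep.int(seq_len(nr), nc)
      j <- rep(seq_len(nc), each = nr)
      cbind(x = (j - 0.5) * config$cellsize, y = (i - 0.5) * config$cellsize)
    }
    ymid <- nr * config$cellsize / 2
    climate <- vector("list", ncl)
    for (l in seq_len(ncl)) {
      v <- config$noise_sd * fields[, l] + config$gradient[l] * (xy[, 2] - ymid)
      climate[[l]] <- matrix(v, nr, nc)
    }
    names(climate) <- paste0("clim", seq_len(ncl))

    nlc <- config$n_landcover
    latents <- vapply(seq_len(nlc + 1),
                      function(l) as.vector(smooth_field(nr, nc, config$autocorr)),
                      numeric(nr * nc))
    expl <- exp(1.5 * latents)
    fracs <- expl / rowSums(expl)
    fracs <- fracs[, seq_len(nlc), drop = FALSE]  # residual class dropped
    colnames(fracs) <- default_landcover_names(nlc)

    # zone effects: climate offsets and landcover homogenisation
    target <- c(0.9, rep(0.02, nlc - 1))  # dominant-agriculture profile
    for (z in config$zones) {
      inz <- area_contains(z$area, xy)
      if (!any(inz)) next
      off <- rep_len(z$climate_offset %||% 0, ncl)
      for (l in seq_len(ncl)) {
        m <- climate[[l]]
        m[inz] <- m[inz] + off[l]
        climate[[l]] <- m
      }
      d <- z$disturbance %||% 0
      if (d > 0)
        fracs[inz, ] <- (1 - d) * fracs[inz, , drop = FALSE] +
          d * matrix(target, sum(inz), nlc, byrow = TRUE)
    }
    landcover <- lapply(seq_len(nlc), function(l) matrix(fracs[, l], nr, nc))
    names(landcover) <- colnames(fracs)
    raster_stack(c(climate, landcover), xmin = 0, ymin = 0,
                 cellsize = config$cellsize)
  })
}

#' Define a species' ground-truth niche
#'
#' Occupancy probability in a cell with environment `e` is
#' `maxprob * exp(-0.5 * sum(((e - optimum) / breadth)^2))`, i.e. an
#' unnormalised Gaussian niche over the named environmental variables,
#' optionally zeroed outside a geographic range.
#'
#' @param id Species label.
#' @param variables Names of the raster layers the niche is defined on.
#' @param optimum Niche optimum per variable (environment units).
#' @param breadth Per-variable niche sd (environment units, strictly
#'   positive). Generalists have larger breadths than specialists.
#' @param maxprob Occupancy probability at the optimum, in `(0, 1]`.
#' @param range Optional [study_area()] restricting where the species can
#'   occur.
#' @return An object of class `species_truth`.
#' @export
species_truth <- function(id, variables, optimum, breadth, maxprob = 1,
                          range = NULL) {
  stopifnot(length(variables) == length(optimum),
            length(optimum) == length(breadth))
  if (any(breadth <= 0)) stop("niche breadths must be strictly positive")
  if (maxprob <= 0 || maxprob > 1) stop("`maxprob` must lie in (0, 1]")
  if (!is.null(range) && !inherits(range, "study_area"))
    stop("`range` must be a study_area or NULL")
  structure(list(id = id, variables = variables,
                 optimum = stats::setNames(as.numeric(optimum), variables),
                 breadth = stats::setNames(as.numeric(breadth), variables),
                 maxprob = maxprob, range = range),
            class = "species_truth")
}

#' Ground-truth occupancy probability per cell
#'
#' @param stack A [raster_stack()] carrying the niche variables.
#' @param truth A [species_truth()].
#' @return Numeric vector of occupancy probabilities, one per cell.
#' @export
occupancy_probability <- function(stack, truth) {
  env <- rs_values(stack, truth$variables)
  z <- sweep(env, 2, truth$optimum, "-")
  z <- sweep(z, 2, truth$breadth, "/")
  p <- truth$maxprob * exp(-0.5 * rowSums(z^2))
  if (!is.null(truth$range)) p[!area_contains(truth$range, rs_xy(stack))] <- 0
  p
}

#' Simulate species occurrence records
#'
#' Samples cells with probability proportional to the truth's occupancy
#' surface, at most one record per cell (1-km2 deduplication); records lie
#' at cell centres.
#'
#' @inheritParams occupancy_probability
#' @param n Number of records (may be 0).
#' @param seed Integer seed.
#' @param area Optional [study_area()]: sample only inside it.
#' @param exclude Optional list of [study_area()]s whose cells are excluded
#'   (used to sample "everything outside the contact zones").
#' @return Data frame with columns `species`, `x`, `y`.
#' @export
simulate_occurrences <- function(stack, truth, n, seed = 1, area = NULL,
                                 exclude = NULL) {
  if (n < 0) stop("`n` must be non-negative")
  p <- occupancy_probability(stack, truth)
  xy <- rs_xy(stack)
  if (!is.null(area)) p[!area_contains(area, xy)] <- 0
  for (ex in exclude) p[area_contains(ex, xy)] <- 0
  if (n == 0)
    return(data.frame(species = character(0), x = numeric(0), y = numeric(0)))
  pos <- which(p > 0)
  if (n > length(pos))
    stop(sprintf("requested %d records but only %d cells have positive occupancy",
                 n, length(pos)))
  cells <- with_seed(seed, {
    if (length(pos) == 1L) pos else sample(pos, n, prob = p[pos])
  })
  data.frame(species = truth$id, x = xy[cells, 1], y = xy[cells, 2])
}

#' Tag occurrence records with area membership
#'
#' @param occ Occurrence data frame with `x`, `y`.
#' @param areas Named list of [study_area()]s (checked in order).
#' @param default Label for records in none of the areas.
#' @return `occ` with an `area` column added.
#' @export
assign_areas <- function(occ, areas, default = "") {
  lab <- rep(default, nrow(occ))
  for (nm in rev(names(areas)))
    lab[area_contains(areas[[nm]], occ[, c("x", "y")])] <- nm
  occ$area <- lab
  occ
}

#' Analytic niche overlap between two Gaussian truths
#'
#' Oracle for recovery tests: compares the `mass` highest-density ellipsoids
#' of two axis-aligned Gaussian niches. Ellipsoid volumes are closed-form
#' (`V = unit-ball-volume(d) * r^d * prod(breadth)` with
#' `r^2 = qchisq(mass, d)`); the intersection is Monte-Carlo integrated by
#' uniform sampling inside each ellipsoid, symmetrised.
#'
#' @param truthA,truthB [species_truth()]s over the same variables.
#' @param mass Probability mass of the highest-density region (default 0.95).
#' @param n_mc Monte-Carlo points per ellipsoid.
#' @param seed Integer seed.
#' @return An `overlap_result` (see [pairwise_overlap()]) without p-values.
#' @export
truth_overlap <- function(truthA, truthB, mass = 0.95, n_mc = 100000,
                          seed = 1) {
  d <- length(truthA$optimum)
  if (length(truthB$optimum) != d)
    stop("truths have different dimensionality")
  r2 <- stats::qchisq(mass, df = d)
  ball <- pi^(d / 2) / gamma(d / 2 + 1)
  vol <- function(tr) ball * r2^(d / 2) * prod(tr$breadth)
  V1 <- vol(truthA); V2 <- vol(truthB)
  # uniform sample inside an axis-aligned ellipsoid
  sample_ellipsoid <- function(tr, m) {
    z <- matrix(stats::rnorm(m * d), m, d)
    z <- z / sqrt(rowSums(z^2))
    rad <- sqrt(r2) * stats::runif(m)^(1 / d)
    pts <- z * rad
    sweep(sweep(pts, 2, tr$breadth, "*"), 2, tr$optimum, "+")
  }
  inside <- function(pts, tr) {
    z <- sweep(sweep(pts, 2, tr$optimum, "-"), 2, tr$breadth, "/")
    rowSums(z^2) <= r2
  }
  I <- with_seed(seed, {
    fA <- mean(inside(sample_ellipsoid(truthA, n_mc), truthB))
    fB <- mean(inside(sample_ellipsoid(truthB, n_mc), truthA))
    0.5 * (V1 * fA + V2 * fB)
  })
  I <- min(I, V1, V2)
  overlap_result(V1, V2, I)
}

#' Write occurrences as CSV
#'
#' Header `species,x,y,area` (area blank when untagged).
#'
#' @param occ Occurrence data frame.
#' @param file Output path.
#' @export
write_occurrences <- function(occ, file) {
  if (is.null(occ$area)) occ$area <- ""
  utils::write.csv(occ[, c("species", "x", "y", "area")], file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a landscape config (and optional truths) as YAML
#'
#' @param config A [landscape_config()].
#' @param file Output path.
#' @param truths Optional named list of [species_truth()]s appended to the
#'   file.
#' @export
write_landscape_config <- function(config, file, truths = NULL) {
  as_plain <- function(x) {
    x <- unclass(x)
    x$zones <- lapply(x$zones, function(z) {
      z$area <- unclass(z$area)
      z
    })
    if (!is.null(x$climate_cor)) x$climate_cor <- as.vector(x$climate_cor)
    x
  }
  out <- list(landscape = as_plain(config))
  if (!is.null(truths))
    out$species <- lapply(truths, function(tr) {
      tr <- unclass(tr)
      if (!is.null(tr$range)) tr$range <- unclass(tr$range)
      lapply(tr, function(el) if (is.numeric(el)) as.vector(el) else el)
    })
  yaml::write_yaml(out, file)
  invisible(file)
}
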