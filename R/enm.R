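# Competition-aware ensemble niche models.
#
# Presence/pseudo-absence logistic regressions where the pseudo-absences
# are drawn inside the competitor species' range (minimum convex polygon),
# encoding biotic exclusion. Per design cell: 30 replicates with fresh
# pseudo-absences and stratified 80/20 splits, the 10 best by test TSS kept
# and averaged into a probability map.

#' Minimum convex polygon of a point set
#'
#' Monotone-chain convex hull; vertices returned counter-clockwise.
#'
#' @param xy Two-column matrix/data frame of planar coordinates, at least 3
#'   non-collinear points (after an optional buffer).
#' @param buffer Fallback half-width (same units as the coordinates): when
#'   the points are fewer than 3 or collinear, each point is inflated to a
#'   square of this half-width before hulling. 0 disables the fallback.
#' @return An object of class `mcp` with `vertices` (counter-clockwise,
#'   not closed) and `area`.
#' @export
minimum_convex_polygon <- function(xy, buffer = 0) {
  xy <- unique(as.matrix(xy[, 1:2, drop = FALSE]))
  degenerate <- nrow(xy) < 3 || {
    v1 <- xy[2, ] - xy[1, ]
    all(abs((xy[, 1] - xy[1, 1]) * v1[2] -
              (xy[, 2] - xy[1, 2]) * v1[1]) < 1e-12)
  }
  if (degenerate) {
    if (buffer <= 0)
      stop("fewer than 3 non-collinear points; supply `buffer` > 0 for a ",
           "buffered fallback range")
    xy <- do.call(rbind, lapply(seq_len(nrow(xy)), function(i)
      cbind(xy[i, 1] + c(-1, -1, 1, 1) * buffer,
            xy[i, 2] + c(-1, 1, -1, 1) * buffer)))
  }
  # Andrew's monotone chain
  o <- order(xy[, 1], xy[, 2])
  pts <- xy[o, , drop = FALSE]
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(p) {
    h <- list()
    for (i in seq_len(nrow(p))) {
      while (length(h) >= 2 &&
             cross(h[[length(h) - 1]], h[[length(h)]], p[i, ]) <= 0)
        h[[length(h)]] <- NULL
      h[[length(h) + 1]] <- p[i, ]
    }
    h
  }
  lower <- build(pts)
  upper <- build(pts[rev(seq_len(nrow(pts))), , drop = FALSE])
  verts <- do.call(rbind, c(lower[-length(lower)], upper[-length(upper)]))
  colnames(verts) <- c("x", "y")
  n <- nrow(verts)
  area <- 0.5 * abs(sum(verts[, 1] * verts[c(2:n, 1), 2] -
                          verts[c(2:n, 1), 1] * verts[, 2]))
  if (area <= 0) stop("degenerate polygon (zero area)")
  structure(list(vertices = verts, area = area), class = "mcp")
}

#' @export
print.mcp <- function(x, ...) {
  cat(sprintf("<mcp> %d vertices, area %.4g\n", nrow(x$vertices), x$area))
  invisible(x)
}

#' Test whether points lie inside a minimum convex polygon
#'
#' Boundary points count as inside.
#'
#' @param mcp An [minimum_convex_polygon()] result.
#' @param xy Two-column matrix/data frame of coordinates.
#' @return Logical vector.
#' @export
point_in_mcp <- function(mcp, xy) {
  xy <- as.matrix(xy[, 1:2, drop = FALSE])
  v <- mcp$vertices
  n <- nrow(v)
  inside <- rep(TRUE, nrow(xy))
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (xy[, 2] - a[2]) - (b[2] - a[2]) * (xy[, 1] - a[1])
    inside <- inside & cr >= -1e-9
  }
  inside
}

#' Sample pseudo-absences inside competitor ranges
#'
#' Cells are drawn uniformly, without replacement, from the grid cells
#' whose centres fall inside the union of the competitor MCPs (and inside
#' `area`, when given), excluding cells that hold presences of the
#' modelled species. Pseudo-absences may fall inside the modelled species'
#' own range where it overlaps a competitor's: only exact presence cells
#' are excluded, preserving the biotic signal in sympatric ground.
#'
#' @param presences Data frame/matrix of presence coordinates (`x`, `y`).
#' @param mcps List of [minimum_convex_polygon()] objects (competitor
#'   ranges; a third species' range may be included).
#' @param stack A [raster_stack()] defining the candidate cells.
#' @param n Number of pseudo-absences; defaults to the presence count.
#' @param area Optional [study_area()] restricting candidates.
#' @param seed Integer seed.
#' @return Data frame with pseudo-absence `x`, `y` at cell centres.
#' @export
sample_pseudo_absences <- function(presences, mcps, stack, n = NULL,
                                   area = NULL, seed = 1) {
  if (inherits(mcps, "mcp")) mcps <- list(mcps)
  pxy <- as.matrix(as.data.frame(presences)[, c("x", "y")])
  n <- n %||% nrow(pxy)
  if (n < 1) stop("`n` must be at least 1")
  cells <- rs_area_cells(stack, area)
  xy <- rs_cell_xy(stack, cells)
  in_union <- rep(FALSE, length(cells))
  for (m in mcps) in_union <- in_union | point_in_mcp(m, xy)
  eligible <- cells[in_union]
  eligible <- setdiff(eligible, rs_cell(stack, pxy))
  if (length(eligible) < n)
    stop(sprintf("only %d eligible cells for %d pseudo-absences",
                 length(eligible), n))
  chosen <- with_seed(seed, {
    if (length(eligible) == 1L) eligible else sample(eligible, n)
  })
  as.data.frame(rs_cell_xy(stack, chosen))
}

#' Ridge-stabilised logistic regression
#'
#' Iteratively reweighted least squares with a tiny L2 penalty that keeps
#' the fit finite under complete separation (a warning is issued when
#' separation is detected). Predictors should be standardised so
#' coefficients are comparable across variables.
#'
#' @param X Numeric predictor matrix (no intercept column).
#' @param y 0/1 response.
#' @param ridge L2 penalty (default 1e-6).
#' @param max_iter,tol IRLS controls: stop when the largest coefficient
#'   change drops below `tol` (default 1e-8) or after `max_iter` (100)
#'   iterations.
#' @return List with `coefficients` (named, `(Intercept)` first),
#'   `fitted`, `converged`, `iterations`, `separation`.
#' @export
fit_glm <- function(X, y, ridge = 1e-6, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(y %in% c(0, 1))) stop("`y` must be 0/1")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant predictor column(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  beta <- numeric(p)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xi * w)
    beta_new <- drop(solve(XtW %*% Xi + diag(ridge, p), XtW %*% z))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(Xi %*% beta)
  separation <- max(abs(eta)) > 30
  if (separation)
    warning("possible complete separation; coefficients ridge-stabilised")
  if (!converged)
    warning(sprintf("IRLS did not converge in %d iterations", max_iter))
  list(coefficients = stats::setNames(beta, colnames(Xi)),
       fitted = stats::plogis(eta), converged = converged,
       iterations = iter, separation = separation)
}

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1`. With `threshold = NULL` the
#' statistic is maximised over all distinct predicted values used as
#' classification thresholds (prediction `>= threshold` counts as
#' presence), ties broken towards the lower threshold.
#'
#' @param obs 0/1 observations with both classes present.
#' @param pred Predicted probabilities (or scores).
#' @param threshold Optional fixed threshold; default maximises TSS.
#' @return List with `tss`, `threshold`, `sensitivity`, `specificity`.
#' @export
tss <- function(obs, pred, threshold = NULL) {
  if (length(obs) != length(pred)) stop("length mismatch")
  if (!all(obs %in% c(0, 1)) || length(unique(obs)) < 2)
    stop("`obs` must contain both 0s and 1s")
  P <- sum(obs == 1); N <- sum(obs == 0)
  if (!is.null(threshold)) {
    yhat <- as.integer(pred >= threshold)
    sens <- sum(yhat == 1 & obs == 1) / P
    spec <- sum(yhat == 0 & obs == 0) / N
    return(list(tss = sens + spec - 1, threshold = threshold,
                sensitivity = sens, specificity = spec))
  }
  o <- order(pred, decreasing = TRUE)
  po <- pred[o]; yo <- obs[o]
  tp <- cumsum(yo); fp <- cumsum(1 - yo)
  last <- which(c(po[-length(po)] != po[-1], TRUE))  # last index per value
  sens <- tp[last] / P
  spec <- 1 - fp[last] / N
  val <- sens + spec - 1
  best <- max(which(val == max(val)))  # lowest threshold among ties
  list(tss = val[best], threshold = po[last][best],
       sensitivity = sens[best], specificity = spec[best])
}

# Standardise raw environment values with stored statistics and append
# quadratic terms when requested.
design_matrix <- function(env, center, scale, quadratic = FALSE) {
  Z <- sweep(sweep(env, 2, center, "-"), 2, scale, "/")
  if (quadratic) {
    Q <- Z^2
    colnames(Q) <- paste0(colnames(Z), "^2")
    Z <- cbind(Z, Q)
  }
  Z
}

ensemble_predict_env <- function(ens, env_raw) {
  Z <- design_matrix(env_raw[, ens$variables, drop = FALSE],
                     ens$center, ens$scale, ens$quadratic)
  Xi <- cbind(1, Z)
  preds <- vapply(ens$replicates[ens$kept], function(r)
    stats::plogis(drop(Xi %*% r$coefficients)), numeric(nrow(Xi)))
  list(mean = rowMeans(preds), sd = apply(preds, 1, stats::sd))
}

#' Fit an ensemble of competition-aware logistic niche models
#'
#' Per replicate: fresh pseudo-absences from the competitor MCP union,
#' a fresh stratified 80/20 presence/absence split, a ridge-stabilised
#' logistic fit on the training fraction (predictors standardised with the
#' training area's cell statistics) and TSS on the test fraction. The
#' `keep` replicates with the highest test TSS are averaged into the
#' ensemble probability map; the per-cell sd across kept replicates is
#' retained as a stability diagnostic.
#'
#' @param presences Data frame of presence coordinates (`x`, `y`).
#' @param stack A [raster_stack()].
#' @param variables Layer names used as predictors (the variable set).
#' @param mcps Competitor range(s): list of [minimum_convex_polygon()]s.
#' @param area Optional [study_area()]: the training area (default whole
#'   grid).
#' @param n_rep Number of replicates (default 30).
#' @param keep Number of best replicates kept (default 10).
#' @param split Training fraction (default 0.8).
#' @param seed Integer master seed.
#' @param quadratic Add quadratic terms (default `FALSE`, linear models).
#' @param label Optional label stored with the ensemble.
#' @return An object of class `enm_ensemble`.
#' @export
fit_ensemble <- function(presences, stack, variables, mcps, area = NULL,
                         n_rep = 30, keep = 10, split = 0.8, seed = 1,
                         quadratic = FALSE, label = NULL) {
  if (keep > n_rep) stop("`keep` cannot exceed `n_rep`")
  if (split <= 0 || split >= 1) stop("`split` must lie in (0, 1)")
  pres_cells <- unique(rs_cell(stack, as.data.frame(presences)[, c("x", "y")]))
  if (anyNA(pres_cells)) stop("presences outside the raster extent")
  n_pres <- length(pres_cells)
  if (n_pres < 20)
    warning(sprintf("only %d unique presence cells; estimates will be unstable",
                    n_pres))
  cells_area <- rs_area_cells(stack, area)
  env_area <- rs_values(stack, variables)[cells_area, , drop = FALSE]
  center <- colMeans(env_area)
  scale <- apply(env_area, 2, stats::sd)
  if (any(scale == 0))
    stop("constant variable(s) over the training area: ",
         paste(variables[scale == 0], collapse = ", "))
  env_all <- rs_values(stack, variables)
  pres_xy <- rs_cell_xy(stack, pres_cells)

  strat_split <- function(n, frac, s) {
    ntr <- max(1L, min(n - 1L, round(frac * n)))
    with_seed(s, sample.int(n, ntr))
  }
  replicates <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    pa <- sample_pseudo_absences(pres_xy, mcps, stack, n = n_pres,
                                 area = area,
                                 seed = child_seed(seed, "pa", r))
    pa_cells <- rs_cell(stack, pa)
    tr_p <- strat_split(n_pres, split, child_seed(seed, "splitp", r))
    tr_a <- strat_split(n_pres, split, child_seed(seed, "splita", r))
    cells <- c(pres_cells, pa_cells)
    y <- rep(c(1, 0), c(n_pres, n_pres))
    Z <- design_matrix(env_all[cells, , drop = FALSE], center, scale,
                       quadratic)
    tr <- c(tr_p, n_pres + tr_a)
    fit <- fit_glm(Z[tr, , drop = FALSE], y[tr])
    te <- setdiff(seq_along(y), tr)
    Xi_te <- cbind(1, Z[te, , drop = FALSE])
    pred_te <- stats::plogis(drop(Xi_te %*% fit$coefficients))
    ev <- tss(y[te], pred_te)
    replicates[[r]] <- list(coefficients = fit$coefficients,
                            test_tss = ev$tss, threshold = ev$threshold,
                            separation = fit$separation,
                            train = tr, cells = cells)
  }
  tss_all <- vapply(replicates, `[[`, numeric(1), "test_tss")
  kept <- order(tss_all, decreasing = TRUE)[seq_len(keep)]

  ens <- structure(list(label = label, variables = variables,
                        center = center, scale = scale,
                        quadratic = quadratic,
                        replicates = replicates, kept = sort(kept),
                        test_tss = tss_all, area = area, seed = seed,
                        train_env = env_area, train_cells = cells_area,
                        stack_info = list(nrow = stack$nrow, ncol = stack$ncol,
                                          xmin = stack$xmin, ymin = stack$ymin,
                                          cellsize = stack$cellsize)),
                   class = "enm_ensemble")
  pr <- ensemble_predict_env(ens, env_area)
  mean_v <- rep(NA_real_, n_cells(stack))
  sd_v <- rep(NA_real_, n_cells(stack))
  mean_v[cells_area] <- pr$mean
  sd_v[cells_area] <- pr$sd
  ens$mean_raster <- rs_from_values(stack, mean_v, "mean")
  ens$sd_raster <- rs_from_values(stack, sd_v, "sd")
  ens$mean_prob <- pr$mean
  ens
}

#' @export
print.enm_ensemble <- function(x, ...) {
  cat(sprintf("<enm_ensemble>%s %d replicates, %d kept | mean kept test TSS %.3f\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              length(x$replicates), length(x$kept),
              mean(x$test_tss[x$kept])))
  cat("  predictors:", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' Variable importance of an ensemble
#'
#' Mean and sd of the standardised logistic coefficients across kept
#' replicates; variables whose mean magnitude exceeds `cutoff` are flagged
#' as most important.
#'
#' @param ensemble An [enm_ensemble][fit_ensemble()].
#' @param cutoff Importance flag threshold on `|mean coefficient|`
#'   (default 0.5, standardised scale).
#' @return Data frame with `variable`, `mean`, `sd`, `important`.
#' @export
variable_importance <- function(ensemble, cutoff = 0.5) {
  co <- vapply(ensemble$replicates[ensemble$kept], `[[`,
               numeric(length(ensemble$replicates[[1]]$coefficients)),
               "coefficients")
  co <- co[-1, , drop = FALSE]  # drop intercept
  data.frame(variable = rownames(co),
             mean = rowMeans(co),
             sd = apply(co, 1, stats::sd),
             important = abs(rowMeans(co)) >= cutoff,
             row.names = NULL)
}

#' Response curve of the averaged model along one variable
#'
#' Default ("observed") variant bins the training-area cells by the raw
#' variable value (equal-width bins over the observed range) and reports
#' the mean averaged-model probability per bin; empty bins are `NA`. The
#' partial-dependence variant holds all other predictors at their
#' training-area mean.
#'
#' @param ensemble An [enm_ensemble][fit_ensemble()].
#' @param variable One of the ensemble's predictor variables.
#' @param n_bins Number of bins (default 25).
#' @param partial Use the partial-dependence variant (default `FALSE`).
#' @return Data frame with `value` (bin midpoint), `probability`,
#'   `n_cells`.
#' @export
response_curve <- function(ensemble, variable, n_bins = 25,
                           partial = FALSE) {
  if (!variable %in% ensemble$variables)
    stop("`variable` is not a predictor of this ensemble")
  v <- ensemble$train_env[, variable]
  rng <- range(v)
  if (partial) {
    grid <- seq(rng[1], rng[2], length.out = n_bins)
    env <- matrix(rep(colMeans(ensemble$train_env), each = n_bins),
                  nrow = n_bins,
                  dimnames = list(NULL, colnames(ensemble$train_env)))
    env[, variable] <- grid
    pr <- ensemble_predict_env(ensemble, env)
    return(data.frame(value = grid, probability = pr$mean,
                      n_cells = NA_integer_))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- cut(v, breaks, include.lowest = TRUE, labels = FALSE)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  prob <- vapply(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    if (!length(idx)) NA_real_ else mean(ensemble$mean_prob[idx])
  }, numeric(1))
  counts <- tabulate(bin, n_bins)
  data.frame(value = mids, probability = prob, n_cells = counts)
}

#' Write ensemble metadata as JSON
#'
#' Seeds, kept replicate ids, per-replicate test TSS and the coefficient
#' table.
#'
#' @param ensemble An [enm_ensemble][fit_ensemble()].
#' @param file Output path.
#' @export
write_ensemble_metadata <- function(ensemble, file) {
  out <- list(label = ensemble$label, variables = ensemble$variables,
              seed = ensemble$seed, kept = ensemble$kept,
              test_tss = ensemble$test_tss,
              importance = variable_importance(ensemble))
  jsonlite::write_json(out, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}
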