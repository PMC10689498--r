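# Kernel-density hypervolume niches in ordination space.
#
# A niche is the region where a Gaussian product-kernel KDE of a species'
# scores exceeds a density threshold chosen so the region retains a fixed
# share (default 95%) of the KDE's probability mass. Volumes are importance
# estimates from samples drawn from the KDE itself; overlap between two
# niches is measured with the Sorensen index K = 2I/(V1+V2) and the overlap
# index OI = I/min(V1,V2), with permutation randomisation tests for
# significance.

#' Silverman per-axis bandwidths
#'
#' `b_j = sd_j * (4 / ((d + 2) * n))^(1 / (d + 4))` for `n` points in `d`
#' dimensions.
#'
#' @param x Numeric matrix of points (n x d), `n >= 2`, every axis with
#'   positive sd.
#' @return Numeric vector of `d` bandwidths.
#' @export
#' @examples
#' silverman_bandwidth(matrix(rnorm(300), ncol = 3))
silverman_bandwidth <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 2) stop("need at least 2 points")
  s <- apply(x, 2, stats::sd)
  if (any(s <= 0)) stop("zero-variance axis: bandwidth undefined")
  s * (4 / ((d + 2) * n))^(1 / (d + 4))
}

#' Build a kernel-density hypervolume
#'
#' Draws `n_mc` samples from the KDE (pick a data point, add axis-wise
#' Gaussian noise), sets the density threshold at the `1 - quantile`
#' quantile of the KDE density evaluated at those samples (so about
#' `quantile` of the KDE's mass lies where the density exceeds it), and
#' estimates the super-level-set volume by importance sampling:
#' `V = mean(1/f over retained samples) * fraction retained`. A set of
#' `n_uniform` representative points, uniform over the region, is kept for
#' overlap estimation.
#'
#' @param x Score matrix (n x d), `n >= d + 1`.
#' @param quantile Probability mass retained inside the region (default
#'   0.95).
#' @param n_uniform Number of uniform representative points (default 1000).
#' @param n_mc Monte-Carlo sample size (default `10000 * d`).
#' @param seed Integer seed; same inputs and seed reproduce the volume and
#'   representative points exactly.
#' @param bandwidth Optional per-axis bandwidths overriding Silverman.
#' @return An object of class `hypervolume` with elements `points`,
#'   `bandwidth`, `threshold`, `volume`, `random_points`, `quantile`,
#'   `n_mc`, `seed`.
#' @export
build_hypervolume <- function(x, quantile = 0.95, n_uniform = 1000,
                              n_mc = NULL, seed = 1, bandwidth = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (quantile <= 0 || quantile >= 1) stop("`quantile` must lie in (0, 1)")
  if (n < d + 1) stop("need at least d + 1 points")
  bw <- bandwidth %||% silverman_bandwidth(x)
  if (length(bw) != d || any(bw <= 0)) stop("invalid bandwidths")
  n_mc <- as.integer(n_mc %||% (10000L * d))
  with_seed(seed, {
    idx <- sample.int(n, n_mc, replace = TRUE)
    noise <- matrix(stats::rnorm(n_mc * d), n_mc, d)
    samp <- x[idx, , drop = FALSE] + sweep(noise, 2, bw, "*")
    dens <- kde_gauss_eval(samp, x, bw)
    thr <- stats::quantile(dens, 1 - quantile, names = FALSE)
    keep <- which(dens >= thr)
    V <- sum(1 / dens[keep]) / n_mc
    ridx <- if (length(keep) == 1L) rep(keep, n_uniform)
            else sample(keep, n_uniform, replace = TRUE, prob = 1 / dens[keep])
    structure(list(points = x, bandwidth = bw, threshold = thr, volume = V,
                   random_points = samp[ridx, , drop = FALSE],
                   quantile = quantile, n_mc = n_mc, seed = seed),
              class = "hypervolume")
  })
}

#' @export
print.hypervolume <- function(x, ...) {
  cat(sprintf("<hypervolume> %d points in %dD, volume %.4g (mass %.2f, n_mc %d)\n",
              nrow(x$points), ncol(x$points), x$volume, x$quantile, x$n_mc))
  invisible(x)
}

# KDE density of a hypervolume evaluated at query points.
hv_density <- function(hv, q) {
  q <- as.matrix(q)
  storage.mode(q) <- "double"
  kde_gauss_eval(q, hv$points, hv$bandwidth)
}

#' Sorensen overlap index K
#'
#' `K = 2 I / (V1 + V2)`: intersection normalised by the mean niche volume;
#' 0 means no overlap, 1 identical niches.
#'
#' @param V1,V2 Niche volumes (positive).
#' @param I Intersection volume, `0 <= I <= min(V1, V2)`.
#' @return K in `[0, 1]`.
#' @export
#' @examples
#' sorensen_index(22.677, 15.517, 11.451)
sorensen_index <- function(V1, V2, I) {
  check_overlap_triple(V1, V2, I)
  2 * I / (V1 + V2)
}

#' Overlap index OI
#'
#' `OI = I / min(V1, V2)`: observed overlap relative to the maximum
#' attainable given the smaller niche (equivalently K divided by its
#' maximum given the two volumes). Preferred over K when the niches differ
#' in size.
#'
#' @inheritParams sorensen_index
#' @return OI in `[0, 1]`; always `>= K`.
#' @export
#' @examples
#' overlap_index(22.677, 15.517, 11.451)
overlap_index <- function(V1, V2, I) {
  check_overlap_triple(V1, V2, I)
  I / min(V1, V2)
}

check_overlap_triple <- function(V1, V2, I) {
  stop_if_not_number(V1, "V1", positive = TRUE)
  stop_if_not_number(V2, "V2", positive = TRUE)
  stop_if_not_number(I, "I")
  if (I < 0) stop("intersection volume must be non-negative")
  if (I > min(V1, V2) * (1 + 1e-9))
    stop("intersection cannot exceed the smaller volume")
  invisible(TRUE)
}

#' Construct an overlap result
#'
#' @param V1,V2 Niche volumes.
#' @param I Intersection volume.
#' @param pK,pOI Optional permutation p-values.
#' @param n_perm Number of permutations behind the p-values.
#' @return Object of class `overlap_result` with `V1`, `V2`, `I`, `K`,
#'   `OI`, `pK`, `pOI`, `n_perm`.
#' @export
overlap_result <- function(V1, V2, I, pK = NA_real_, pOI = NA_real_,
                           n_perm = NA_integer_) {
  structure(list(V1 = V1, V2 = V2, I = I,
                 K = sorensen_index(V1, V2, I),
                 OI = overlap_index(V1, V2, I),
                 pK = pK, pOI = pOI, n_perm = n_perm),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> V1 %.4g, V2 %.4g, I %.4g | K %.3f, OI %.3f",
              x$V1, x$V2, x$I, x$K, x$OI))
  if (!is.na(x$pK)) cat(sprintf(" | pK %.3f, pOI %.3f (%d perms)",
                                x$pK, x$pOI, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Pairwise overlap of two hypervolumes
#'
#' Estimates the intersection volume symmetrically from each hypervolume's
#' uniform representative points:
#' `I = (V1 * frac(points of 1 inside 2) + V2 * frac(points of 2 inside 1)) / 2`.
#' Monte-Carlo noise occasionally pushes I above `min(V1, V2)`; such
#' excursions are clipped with a warning.
#'
#' @param hv1,hv2 [hypervolume][build_hypervolume()]s in the same score
#'   space.
#' @return An [overlap_result()] without p-values.
#' @export
pairwise_overlap <- function(hv1, hv2) {
  if (ncol(hv1$points) != ncol(hv2$points))
    stop("hypervolumes have different dimensionality")
  f21 <- hv_density(hv2, hv1$random_points)
  f12 <- hv_density(hv1, hv2$random_points)
  I <- 0.5 * (hv1$volume * mean(f21 >= hv2$threshold) +
                hv2$volume * mean(f12 >= hv1$threshold))
  vmin <- min(hv1$volume, hv2$volume)
  if (I > vmin) {
    excess <- (I - vmin) / vmin
    warning(sprintf(
      "intersection exceeded min(V1, V2) by %.2f%% (MC noise); clipped",
      100 * excess))
    I <- vmin
  }
  overlap_result(hv1$volume, hv2$volume, I)
}

# Null and observed statistics shared by the two permutation p-values:
# rebuilds both hypervolumes (bandwidths re-estimated per split) for the
# observed labelling and for each random relabelling of the pooled scores.
perm_null_stats <- function(a, b, n_perm, seed, quantile, n_uniform, n_mc) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("score sets have different dimensionality")
  na <- nrow(a); nb <- nrow(b)
  one <- function(xa, xb, tag, k) {
    h1 <- build_hypervolume(xa, quantile = quantile, n_uniform = n_uniform,
                            n_mc = n_mc,
                            seed = child_seed(seed, paste0(tag, "A"), k))
    h2 <- build_hypervolume(xb, quantile = quantile, n_uniform = n_uniform,
                            n_mc = n_mc,
                            seed = child_seed(seed, paste0(tag, "B"), k))
    ov <- suppressWarnings(pairwise_overlap(h1, h2))
    c(K = ov$K, OI = ov$OI)
  }
  obs <- one(a, b, "obs", 0L)
  pool <- rbind(a, b)
  null <- matrix(NA_real_, n_perm, 2, dimnames = list(NULL, c("K", "OI")))
  for (k in seq_len(n_perm)) {
    idx <- with_seed(child_seed(seed, "permsplit", k), sample.int(na + nb))
    null[k, ] <- one(pool[idx[seq_len(na)], , drop = FALSE],
                     pool[idx[na + seq_len(nb)], , drop = FALSE],
                     "perm", k)
  }
  list(observed = obs, null = null)
}

#' Permutation randomisation test of niche overlap
#'
#' Pools the two score sets, randomly re-splits them into groups of the
#' original sizes, rebuilds both hypervolumes per split (bandwidths
#' re-estimated) and recomputes the overlap statistic. The default
#' alternative is segregation: observed overlap lower than expected under
#' random relabelling, `p = (1 + #{null <= observed}) / (n_perm + 1)`.
#'
#' @param a,b Score matrices (each with at least d + 1 rows).
#' @param n_perm Number of permutations (default 100).
#' @param statistic `"K"` or `"OI"`.
#' @param alternative `"less"` (segregation, default) or `"two.sided"`.
#' @param seed Integer master seed; permutation seeds derive from it.
#' @param quantile,n_uniform,n_mc Passed to [build_hypervolume()]; `n_mc`
#'   may be reduced for speed since the null only needs the statistic's
#'   distribution.
#' @return List of class `overlap_permutation`: `p.value`, `observed`,
#'   `null` (vector), `statistic`, `alternative`, `n_perm`.
#' @export
permutation_overlap_test <- function(a, b, n_perm = 100,
                                     statistic = c("K", "OI"),
                                     alternative = c("less", "two.sided"),
                                     seed = 1, quantile = 0.95,
                                     n_uniform = 1000, n_mc = NULL) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  st <- perm_null_stats(a, b, n_perm, seed, quantile, n_uniform, n_mc)
  obs <- st$observed[[statistic]]
  null <- st$null[, statistic]
  p_less <- (1 + sum(null <= obs)) / (n_perm + 1)
  p <- if (alternative == "less") p_less
       else min(1, 2 * min(p_less, (1 + sum(null >= obs)) / (n_perm + 1)))
  structure(list(p.value = p, observed = obs, null = null,
                 statistic = statistic, alternative = alternative,
                 n_perm = n_perm),
            class = "overlap_permutation")
}

#' @export
print.overlap_permutation <- function(x, ...) {
  cat(sprintf("<overlap_permutation> %s = %.3f, p = %.4f (%s, %d perms)\n",
              x$statistic, x$observed, x$p.value, x$alternative, x$n_perm))
  invisible(x)
}

#' Hypervolume of an area's environmental background
#'
#' Uniformly subsamples the area's cells, projects them into the fitted
#' ordination and builds a hypervolume. Used for environmental-variability
#' comparisons between areas.
#'
#' @param stack A [raster_stack()].
#' @param area A [study_area()] or `NULL` for the whole grid.
#' @param model A [pca_model][fit_pca()].
#' @param n Number of background cells (default 2000; all cells if fewer).
#' @param k Components (default 3).
#' @param seed Integer seed.
#' @param ... Passed to [build_hypervolume()].
#' @return A list with `hypervolume` and the background `scores`.
#' @export
background_hypervolume <- function(stack, area, model, n = 2000, k = 3,
                                   seed = 1, ...) {
  cells <- rs_area_cells(stack, area)
  if (length(cells) > n)
    cells <- with_seed(child_seed(seed, "bgcells", 0L), sample(cells, n))
  env <- rs_values(stack, model$variables)[cells, , drop = FALSE]
  sc <- project_scores(model, env, k = k)
  list(hypervolume = build_hypervolume(sc, seed = child_seed(seed, "bghv", 0L),
                                       ...),
       scores = sc)
}

#' Assemble overlap results into a report table
#'
#' @param results Named list of [overlap_result()]s; names become the
#'   `comparison` column (optionally `"comparison|space"`).
#' @param alpha Significance level for the flag (default 0.05).
#' @return Data frame with columns
#'   `comparison,space,V1,V2,I,K,OI,pK,pOI,signif`.
#' @export
overlap_table <- function(results, alpha = 0.05) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    data.frame(comparison = parts[1],
               space = if (length(parts) > 1) parts[2] else "",
               V1 = r$V1, V2 = r$V2, I = r$I, K = r$K, OI = r$OI,
               pK = r$pK, pOI = r$pOI,
               signif = !is.na(r$pK) & (r$pK < alpha | r$pOI < alpha))
  })
  do.call(rbind, rows)
}

#' Write an overlap table as CSV
#'
#' @param tab Data frame from [overlap_table()].
#' @param file Output path.
#' @export
write_overlap_table <- function(tab, file) {
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
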