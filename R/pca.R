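# Shared environmental ordination. Climate and landcover variability are
# summarised by separate PCAs fitted on the background cells of the large
# study area; occurrences and zone backgrounds are then projected into that
# one space so volumes are comparable across areas.

#' Fit a principal component analysis of environmental samples
#'
#' PCA of the correlation matrix by default (variables standardised), since
#' environmental variables mix units (degrees, mm, fraction cover). Loading
#' signs are fixed so each column's largest-magnitude entry is positive,
#' making the decomposition deterministic.
#'
#' @param x Numeric matrix/data frame (samples x variables), no missing
#'   values, at least 2 rows.
#' @param standardize Standardise variables (correlation PCA) or not
#'   (covariance PCA).
#' @return An object of class `pca_model` with elements `variables`,
#'   `center`, `scale`, `loadings` (orthonormal columns), `eigenvalues`
#'   (non-increasing) and `var_fraction`.
#' @export
fit_pca <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to fit a PCA")
  if (anyNA(x)) stop("missing values are not allowed")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  s <- apply(x, 2, stats::sd)
  if (standardize && any(s <= 0))
    stop("constant variable(s) under standardization: ",
         paste(colnames(x)[s <= 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  rot <- pc$rotation
  for (k in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) rot[, k] <- -rot[, k]
  }
  ev <- pc$sdev^2
  structure(list(variables = colnames(x),
                 center = pc$center,
                 scale = if (standardize) pc$scale
                         else stats::setNames(rep(1, ncol(x)), colnames(x)),
                 loadings = rot,
                 eigenvalues = ev,
                 var_fraction = ev / sum(ev),
                 standardized = standardize),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d variables (%s PCA)\n", length(x$variables),
              if (x$standardized) "correlation" else "covariance"))
  k <- min(3, length(x$eigenvalues))
  cat("  variance fraction pc1..pc", k, ": ",
      paste(sprintf("%.3f", x$var_fraction[1:k]), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Project environmental values into a fitted PCA space
#'
#' Standardises with the training means/sds, then rotates. Projecting the
#' training data reproduces the fit's scores.
#'
#' @param model A [pca_model][fit_pca()].
#' @param newdata Matrix/data frame carrying (at least) the model variables.
#' @param k Number of leading components to return (default 3, the
#'   dimensionality used for hypervolumes).
#' @return Score matrix (rows x k), columns `pc1..pck`.
#' @export
project_scores <- function(model, newdata, k = 3) {
  newdata <- as.matrix(as.data.frame(newdata)[, model$variables, drop = FALSE])
  if (anyNA(newdata)) stop("missing values are not allowed")
  if (k > ncol(model$loadings)) stop("`k` exceeds the model rank")
  z <- sweep(sweep(newdata, 2, model$center, "-"), 2, model$scale, "/")
  sc <- z %*% model$loadings[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("pc", seq_len(k))
  sc
}

#' Variance contributions of the leading components
#'
#' @param model A [pca_model][fit_pca()].
#' @param k Number of components (default 3).
#' @return Named numeric vector of variance fractions.
#' @export
variance_contributions <- function(model, k = 3) {
  k <- min(k, length(model$var_fraction))
  stats::setNames(model$var_fraction[seq_len(k)], paste0("pc", seq_len(k)))
}

#' Drop highly correlated variables
#'
#' Greedy pairwise filter: while any pair exceeds the absolute-correlation
#' threshold, drop the member of the worst pair with the larger mean
#' absolute correlation to everything else.
#'
#' @param x Numeric matrix/data frame.
#' @param threshold Absolute Pearson correlation cutoff (default 0.7).
#' @return Character vector of retained variable names.
#' @export
correlation_filter <- function(x, threshold = 0.7) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  keep <- colnames(x)
  repeat {
    if (length(keep) < 2) break
    r <- abs(stats::cor(x[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    mean_r <- rowMeans(r)
    drop_var <- keep[worst[which.max(mean_r[worst])]]
    keep <- setdiff(keep, drop_var)
  }
  keep
}

#' Write PCA scores as CSV
#'
#' Columns `id,area,species,pc1..pck`.
#'
#' @param scores Score matrix from [project_scores()].
#' @param file Output path.
#' @param id,area,species Optional annotation vectors recycled to the score
#'   rows.
#' @export
write_scores <- function(scores, file, id = seq_len(nrow(scores)),
                         area = "", species = "") {
  df <- data.frame(id = id, area = rep_len(area, nrow(scores)),
                   species = rep_len(species, nrow(scores)))
  utils::write.csv(cbind(df, as.data.frame(scores)), file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Persist a PCA model as JSON
#'
#' @param model A [pca_model][fit_pca()].
#' @param file Output path.
#' @export
write_pca_model <- function(model, file) {
  out <- list(variables = model$variables,
              center = as.vector(model$center),
              scale = as.vector(model$scale),
              loadings = model$loadings,
              eigenvalues = model$eigenvalues,
              var_fraction = model$var_fraction,
              standardized = model$standardized)
  jsonlite::write_json(out, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}
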