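# Cross-area model transfer: projection with source standardisation,
# extrapolation detection (MESS) and calibration scoring (TSS, Miller).

#' Project an ensemble onto a target raster
#'
#' Averaged kept-replicate predictions using the source area's
#' standardisation statistics (the target is deliberately not
#' re-standardised: transfer asks how the fitted response performs under
#' the target's absolute conditions).
#'
#' @param ensemble An [enm_ensemble][fit_ensemble()].
#' @param target_stack A [raster_stack()] carrying all model variables.
#' @param area Optional [study_area()] restricting the projection.
#' @return A single-layer [raster_stack()] (`mean`) with `NA` outside
#'   `area`.
#' @export
project_ensemble <- function(ensemble, target_stack, area = NULL) {
  missing <- setdiff(ensemble$variables, names(target_stack))
  if (length(missing))
    stop("target stack lacks model variable(s): ",
         paste(missing, collapse = ", "))
  cells <- rs_area_cells(target_stack, area)
  env <- rs_values(target_stack, ensemble$variables)[cells, , drop = FALSE]
  pr <- ensemble_predict_env(ensemble, env)
  v <- rep(NA_real_, n_cells(target_stack))
  v[cells] <- pr$mean
  rs_from_values(target_stack, v, "mean")
}

#' Multivariate environmental similarity surface (MESS)
#'
#' For each point and variable, with `f` the percentage of reference values
#' below the point value: `f = 0` gives `100 * (p - min) / (max - min)`;
#' `0 < f <= 50` gives `2f`; `50 < f < 100` gives `2(100 - f)`; `f = 100`
#' gives `100 * (max - p) / (max - min)`. The MESS score is the minimum
#' across variables; negative values flag conditions outside the reference
#' (extrapolation).
#'
#' @param reference Matrix/data frame of training-sample values (the model
#'   domain), one column per variable.
#' @param points Matrix/data frame of the same variables at the query
#'   points.
#' @return Numeric vector of MESS scores (one per query row) with the
#'   per-variable similarity matrix attached as attribute `"similarity"`.
#' @export
mess <- function(reference, points) {
  reference <- as.matrix(reference)
  points <- as.matrix(as.data.frame(points)[,
    colnames(reference) %||% seq_len(ncol(reference)), drop = FALSE])
  if (nrow(reference) < 1) stop("empty reference sample")
  sim <- matrix(NA_real_, nrow(points), ncol(points),
                dimnames = list(NULL, colnames(reference)))
  for (j in seq_len(ncol(points))) {
    refv <- sort(reference[, j])
    rmin <- refv[1]; rmax <- refv[length(refv)]
    if (rmax == rmin)
      stop("degenerate reference range for variable ",
           colnames(reference)[j] %||% j)
    p <- points[, j]
    f <- 100 * findInterval(p, refv, left.open = TRUE) / length(refv)
    s <- ifelse(f == 0, 100 * (p - rmin) / (rmax - rmin),
         ifelse(f <= 50, 2 * f,
         ifelse(f < 100, 2 * (100 - f),
                100 * (rmax - p) / (rmax - rmin))))
    sim[, j] <- s
  }
  out <- apply(sim, 1, min)
  attr(out, "similarity") <- sim
  out
}

#' MESS raster for an ensemble on a target stack
#'
#' Reference sample = the cells of the ensemble's training area (the model
#' domain, not just presences).
#'
#' @inheritParams project_ensemble
#' @return Single-layer [raster_stack()] (`mess`).
#' @export
mess_raster <- function(ensemble, target_stack, area = NULL) {
  cells <- rs_area_cells(target_stack, area)
  env <- rs_values(target_stack, ensemble$variables)[cells, , drop = FALSE]
  m <- mess(ensemble$train_env, env)
  v <- rep(NA_real_, n_cells(target_stack))
  v[cells] <- as.numeric(m)
  rs_from_values(target_stack, v, "mess")
}

#' Miller's calibration regression
#'
#' Logistic regression of the observations on the logit of the predicted
#' probabilities: a perfectly calibrated model gives intercept 0 and slope
#' 1. Under this (recalibration) convention systematic overprediction
#' yields a negative intercept; because overestimation is often verbally
#' reported with the opposite sign, the sign-flipped intercept is also
#' returned as `intercept_overestimation` (positive = overprediction).
#'
#' @param obs 0/1 observations with both classes present.
#' @param pred Predicted probabilities; clipped to
#'   `[1e-6, 1 - 1e-6]` before the logit.
#' @return List with `intercept`, `slope`, `intercept_overestimation`.
#' @export
miller_calibration <- function(obs, pred) {
  if (length(unique(obs)) < 2)
    stop("`obs` must contain both 0s and 1s")
  lp <- stats::qlogis(pmin(pmax(pred, 1e-6), 1 - 1e-6))
  if (stats::sd(lp) == 0)
    stop("constant predictions: calibration slope undefined")
  fit <- stats::glm(obs ~ lp, family = stats::binomial())
  co <- unname(stats::coef(fit))
  list(intercept = co[1], slope = co[2],
       intercept_overestimation = -co[1])
}

#' Evaluate an ensemble transferred to another area
#'
#' Projects the ensemble, draws target-area pseudo-absences with the same
#' competitor-MCP rule, and scores the projection with TSS, Miller's
#' calibration and the MESS extrapolation fraction.
#'
#' @param ensemble An [enm_ensemble][fit_ensemble()].
#' @param target_stack Target [raster_stack()].
#' @param target_records Data frame of the species' records in the target
#'   area (`x`, `y`), non-empty.
#' @param mcps Competitor MCP(s) in the target area.
#' @param area Optional target [study_area()].
#' @param seed Integer seed for the pseudo-absence draw.
#' @return Object of class `transfer_report`: `tss`, `threshold`,
#'   `miller` (list), `mess_raster`, `extrapolation_fraction`,
#'   `n_presence`, `n_absence`, plus the projected `raster`.
#' @export
evaluate_transfer <- function(ensemble, target_stack, target_records, mcps,
                              area = NULL, seed = 1) {
  target_records <- as.data.frame(target_records)
  if (nrow(target_records) == 0) stop("no target records")
  proj <- project_ensemble(ensemble, target_stack, area = area)
  pa <- sample_pseudo_absences(target_records, mcps, target_stack,
                               area = area,
                               seed = child_seed(seed, "transfer_pa", 0L))
  xy <- rbind(as.matrix(target_records[, c("x", "y")]), as.matrix(pa))
  obs <- rep(c(1, 0), c(nrow(target_records), nrow(pa)))
  env <- rs_extract(target_stack, xy, ensemble$variables)
  pred <- ensemble_predict_env(ensemble, env)$mean
  ev <- tss(obs, pred)
  mc <- tryCatch(miller_calibration(obs, pred), error = function(e) {
    warning("Miller calibration unavailable: ", conditionMessage(e))
    list(intercept = NA_real_, slope = NA_real_,
         intercept_overestimation = NA_real_)
  })
  mr <- mess_raster(ensemble, target_stack, area = area)
  mv <- as.vector(mr$layers$mess)
  structure(list(tss = ev$tss, threshold = ev$threshold, miller = mc,
                 mess_raster = mr,
                 extrapolation_fraction = mean(mv[!is.na(mv)] < 0),
                 n_presence = nrow(target_records), n_absence = nrow(pa),
                 raster = proj),
            class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat(sprintf(
    "<transfer_report> TSS %.3f | Miller intercept %.3f, slope %.3f | %.1f%% extrapolated\n",
    x$tss, x$miller$intercept, x$miller$slope,
    100 * x$extrapolation_fraction))
  invisible(x)
}
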