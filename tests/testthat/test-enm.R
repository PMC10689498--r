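# Ensemble niche models: convex-hull ranges, competitor-constrained
# pseudo-absences, ridge logistic regression, TSS and ensemble averaging.

test_that("minimum convex polygon recovers known hulls", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5), c(0.2, 0.7))
  h <- minimum_convex_polygon(sq)
  expect_equal(h$area, 1)
  expect_equal(nrow(h$vertices), 4)
  expect_true(all(point_in_mcp(h, sq)))

  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(minimum_convex_polygon(tri)$area, 6)

  set.seed(1)
  pts <- matrix(rnorm(400), ncol = 2)
  h2 <- minimum_convex_polygon(pts)
  # reference-implementation oracle: grDevices::chull + shoelace
  ch <- grDevices::chull(pts)
  v <- pts[ch, ]
  n <- nrow(v)
  shoelace <- 0.5 * abs(sum(v[, 1] * v[c(2:n, 1), 2] -
                              v[c(2:n, 1), 1] * v[, 2]))
  expect_equal(h2$area, shoelace, tolerance = 1e-12)
  expect_true(all(point_in_mcp(h2, pts)))
  # counter-clockwise orientation: signed shoelace area positive
  w <- h2$vertices; m <- nrow(w)
  expect_gt(sum(w[, 1] * w[c(2:m, 1), 2] - w[c(2:m, 1), 1] * w[, 2]), 0)
})

test_that("degenerate point sets error without a buffer and hull with one", {
  line <- cbind(1:5, 2 * (1:5))
  expect_error(minimum_convex_polygon(line), "buffer")
  h <- minimum_convex_polygon(line, buffer = 1)
  expect_gt(h$area, 0)
  expect_true(all(point_in_mcp(h, line)))
  expect_error(minimum_convex_polygon(rbind(c(0, 0), c(1, 1))), "buffer")
})

test_that("pseudo-absences respect the competitor range, presence cells and count", {
  st <- tiny_stack(12, 12)
  mcp <- minimum_convex_polygon(rbind(c(1, 1), c(9, 1), c(9, 9), c(1, 9)))
  pres <- data.frame(x = c(2.5, 3.5, 4.5), y = c(2.5, 2.5, 2.5))
  pa <- sample_pseudo_absences(pres, mcp, st, seed = 1)
  expect_equal(nrow(pa), nrow(pres))  # defaults to the presence count
  expect_true(all(point_in_mcp(mcp, pa)))
  expect_length(intersect(rs_cell(st, pa), rs_cell(st, pres)), 0)
  expect_error(sample_pseudo_absences(pres, mcp, st, n = 1000, seed = 1),
               "eligible")
})

test_that("pseudo-absence draws are uniform over eligible cells", {
  st <- tiny_stack(6, 6)
  mcp <- minimum_convex_polygon(rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5)))
  pres <- data.frame(x = 0.5, y = 0.5)
  eligible <- setdiff(rs_area_cells(st, study_area("a", 0, 5, 0, 5)),
                      rs_cell(st, pres))
  counts <- stats::setNames(rep(0, length(eligible)), eligible)
  for (r in 1:500) {
    pa <- sample_pseudo_absences(pres, mcp, st, n = 5, seed = r)
    hit <- as.character(rs_cell(st, pa))
    counts[hit] <- counts[hit] + 1
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("ridge logistic regression recovers, nulls out and survives separation", {
  set.seed(2)
  X <- matrix(rnorm(2000 * 3), ncol = 3)
  colnames(X) <- c("x1", "x2", "x3")
  y0 <- rbinom(2000, 1, 0.5)  # independent of X
  f0 <- fit_glm(X, y0)
  expect_true(all(abs(f0$coefficients[-1]) < 0.1))
  expect_true(f0$converged)

  y1 <- rbinom(2000, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 2]))
  f1 <- fit_glm(X, y1)
  expect_equal(unname(f1$coefficients[c("x1", "x2")]), c(0.8, -0.5),
               tolerance = 0.2)
  # agreement with the standard IRLS implementation
  ref <- stats::glm.fit(cbind(1, X), y1, family = stats::binomial())
  expect_equal(unname(f1$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)

  sep <- matrix(c(seq(-1, -0.1, length.out = 10),
                  seq(0.1, 1, length.out = 10)), ncol = 1)
  colnames(sep) <- "x"
  ysep <- rep(c(0, 1), each = 10)
  expect_warning(fs <- fit_glm(sep, ysep), "separation")
  expect_true(all(is.finite(fs$coefficients)))
  expect_lt(min(fs$fitted), 0.01)
  expect_gt(max(fs$fitted), 0.99)

  expect_error(fit_glm(cbind(const = rep(1, 10)), rep(0:1, 5)), "constant")
})

test_that("TSS matches direct confusion arithmetic and is maximised over thresholds", {
  obs <- rep(c(1, 0), c(50, 50))
  pred <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 15), rep(0.1, 35))
  # TP 40, FN 10, TN 35, FP 15 at theta = 0.5
  at <- tss(obs, pred, threshold = 0.5)
  expect_equal(at$tss, 0.8 + 0.7 - 1)

  perfect <- tss(obs, c(rep(0.99, 50), rep(0.01, 50)))
  expect_equal(perfect$tss, 1)

  set.seed(3)
  null <- tss(rbinom(5000, 1, 0.5), runif(5000))
  expect_lte(null$tss, 0.1)

  # maximised value never below any fixed-threshold value
  set.seed(4)
  o <- rbinom(200, 1, 0.5); p <- runif(200)
  best <- tss(o, p)
  for (th in c(0.25, 0.5, 0.75))
    expect_gte(best$tss, tss(o, p, threshold = th)$tss)
  expect_error(tss(rep(1, 10), runif(10)), "both")
})

# deterministic suitability on a gradient landscape shared by the
# ensemble tests below
ens_fixture <- local({
  nr <- 30; nc <- 30
  st <- generate_environment(landscape_config(
    nrow = nr, ncol = nc, n_climate = 2, n_landcover = 2,
    gradient = c(0.2, 0), noise_sd = 0.3, autocorr = 3, seed = 41))
  v <- rs_values(st, "clim1")[, 1]
  pres_cells <- which(v > stats::quantile(v, 0.8))
  pres <- as.data.frame(contactniche:::rs_cell_xy(st, pres_cells))
  corners <- rbind(c(0, 0), c(nc, 0), c(nc, nr), c(0, nr))
  list(st = st, pres = pres, mcp = minimum_convex_polygon(corners))
})

test_that("ensembles separate a hard-threshold species and keep the best replicates", {
  fx <- ens_fixture
  ens <- suppressWarnings(fit_ensemble(fx$pres, fx$st, c("clim1", "clim2"),
                                       fx$mcp, n_rep = 10, keep = 4, seed = 1))
  expect_gt(mean(ens$test_tss[ens$kept]), 0.9)
  expect_gte(min(ens$test_tss[ens$kept]),
             max(ens$test_tss[-ens$kept]))
  mv <- contactniche:::rs_values(ens$mean_raster)[, 1]
  expect_true(all(mv >= 0 & mv <= 1))
  # every replicate pairs each presence with one pseudo-absence
  for (r in ens$replicates)
    expect_length(r$cells, 2 * nrow(unique(fx$pres)))

  # identical master seed reproduces the ensemble exactly
  ens2 <- suppressWarnings(fit_ensemble(fx$pres, fx$st, c("clim1", "clim2"),
                                        fx$mcp, n_rep = 10, keep = 4, seed = 1))
  expect_identical(ens$mean_prob, ens2$mean_prob)
  expect_identical(ens$test_tss, ens2$test_tss)

  # keep = n_rep disables selection
  all_kept <- suppressWarnings(fit_ensemble(fx$pres, fx$st,
                                            c("clim1", "clim2"), fx$mcp,
                                            n_rep = 5, keep = 5, seed = 2))
  expect_equal(all_kept$kept, 1:5)
  expect_error(fit_ensemble(fx$pres, fx$st, c("clim1", "clim2"), fx$mcp,
                            n_rep = 5, keep = 6), "exceed")
})

test_that("variable importance recovers signs and flags strong effects", {
  fx <- ens_fixture
  ens <- suppressWarnings(fit_ensemble(fx$pres, fx$st, c("clim1", "clim2"),
                                       fx$mcp, n_rep = 8, keep = 4, seed = 3))
  imp <- variable_importance(ens)
  expect_equal(nrow(imp), 2)
  expect_gt(imp$mean[imp$variable == "clim1"], 0.5)
  expect_true(imp$important[imp$variable == "clim1"])
  expect_lt(abs(imp$mean[imp$variable == "clim2"]),
            abs(imp$mean[imp$variable == "clim1"]))
  f <- withr::local_tempfile(fileext = ".json")
  write_ensemble_metadata(ens, f)
  expect_equal(jsonlite::read_json(f, simplifyVector = TRUE)$kept, ens$kept)
})

test_that("response curves are monotone for a monotone effect and NA in empty bins", {
  fx <- ens_fixture
  ens <- suppressWarnings(fit_ensemble(fx$pres, fx$st, c("clim1", "clim2"),
                                       fx$mcp, n_rep = 8, keep = 4, seed = 4))
  rc <- response_curve(ens, "clim1", n_bins = 12)
  ok <- !is.na(rc$probability)
  expect_gt(stats::cor(rc$value[ok], rc$probability[ok], method = "spearman"),
            0.9)
  pd <- response_curve(ens, "clim1", n_bins = 12, partial = TRUE)
  expect_gt(stats::cor(pd$value, pd$probability, method = "spearman"), 0.9)
  expect_error(response_curve(ens, "not_a_layer"), "not a predictor")

  # a gap in the training values yields missing (not zero) bins
  gap <- ens
  gap$train_env[, "clim1"] <- c(seq(0, 1, length.out = 450),
                                seq(4, 5, length.out = 450))
  gap$mean_prob <- rep(0.5, 900)
  rc2 <- response_curve(gap, "clim1", n_bins = 10)
  expect_true(any(is.na(rc2$probability)))
  expect_true(all(rc2$n_cells[is.na(rc2$probability)] == 0))
})

test_that("a constant averaged map gives a flat observed response curve", {
  fx <- ens_fixture
  ens <- suppressWarnings(fit_ensemble(fx$pres, fx$st, c("clim1", "clim2"),
                                       fx$mcp, n_rep = 4, keep = 2, seed = 5))
  flat <- ens
  flat$mean_prob <- rep(0.42, length(ens$mean_prob))
  rc <- response_curve(flat, "clim1", n_bins = 8)
  expect_lt(diff(range(rc$probability, na.rm = TRUE)), 1e-9)
})
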