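# Synthetic landscape generator: analytic gradients, determinism,
# correlation targets, landcover composition, disturbance effects and
# occurrence sampling against the known occupancy surface.

test_that("zero-noise configuration reproduces the analytic gradient at cell centres", {
  cfg <- landscape_config(nrow = 20, ncol = 15, n_climate = 2,
                          n_landcover = 2, noise_sd = 0,
                          gradient = c(0.1, -0.05), seed = 3)
  st <- generate_environment(cfg)
  xy <- contactniche:::rs_xy(st)
  ymid <- 20 / 2
  expect_equal(unname(rs_values(st, "clim1")[, 1]), 0.1 * (xy[, "y"] - ymid))
  expect_equal(unname(rs_values(st, "clim2")[, 1]), -0.05 * (xy[, "y"] - ymid))
})

test_that("identical config and seed give a bit-identical stack", {
  cfg <- landscape_config(nrow = 25, ncol = 25, seed = 11)
  expect_identical(generate_environment(cfg), generate_environment(cfg))
  cfg2 <- landscape_config(nrow = 25, ncol = 25, seed = 12)
  expect_false(identical(generate_environment(cfg)$layers$clim1,
                         generate_environment(cfg2)$layers$clim1))
})

test_that("inter-layer correlation targets are met empirically", {
  R <- matrix(c(1, 0.8, 0.8, 1), 2)
  cfg <- landscape_config(nrow = 200, ncol = 200, n_climate = 2,
                          n_landcover = 2, gradient = c(0, 0),
                          climate_cor = R, autocorr = 4, seed = 21)
  st <- generate_environment(cfg)
  v <- rs_values(st, c("clim1", "clim2"))
  expect_lt(abs(stats::cor(v[, 1], v[, 2]) - 0.8), 0.05)
})

test_that("config validation rejects bad inputs", {
  expect_error(landscape_config(nrow = -5), "positive")
  badR <- matrix(c(1, 0.5, 0.9, 1), 2)  # asymmetric
  expect_error(landscape_config(n_climate = 2, climate_cor = badR),
               "symmetric")
  notpsd <- matrix(c(1, 2, 2, 1), 2)
  expect_error(landscape_config(n_climate = 2, climate_cor = notpsd),
               "semi-definite")
  zone <- list(area = study_area("z", 0, 5, 0, 5), disturbance = 1.5)
  expect_error(landscape_config(zones = list(zone)), "\\[0, 1\\]")
})

test_that("landcover layers are fractions summing to at most one per cell", {
  cfg <- landscape_config(nrow = 40, ncol = 40, seed = 5)
  st <- generate_environment(cfg)
  lc <- rs_values(st, setdiff(names(st), paste0("clim", 1:9)))
  expect_true(all(lc >= 0 & lc <= 1))
  expect_true(all(rowSums(lc) <= 1 + 1e-12))
})

test_that("disturbance raises the agriculture fraction cellwise and lowers evenness", {
  zone <- study_area("z", 5, 25, 5, 25)
  mk <- function(d) generate_environment(landscape_config(
    nrow = 30, ncol = 30, seed = 9,
    zones = list(list(area = zone, disturbance = d))))
  st0 <- mk(0); st1 <- mk(0.8)
  cells <- rs_area_cells(st0, zone)
  lcn <- setdiff(names(st0), paste0("clim", 1:9))
  lc0 <- rs_values(st0, lcn)[cells, ]
  lc1 <- rs_values(st1, lcn)[cells, ]
  # same seed: undisturbed composition identical, agriculture only goes up
  expect_true(all(lc1[, "agriculture"] >= lc0[, "agriculture"]))
  ev0 <- apply(lc0, 1, shannon_evenness)
  ev1 <- apply(lc1, 1, shannon_evenness)
  expect_lt(mean(ev1), mean(ev0))
  # climate untouched outside the offset mechanism
  expect_equal(st0$layers$clim1, st1$layers$clim1)
})

test_that("occurrence sampling honours edge cases and the occupancy surface", {
  st <- tiny_stack(8, 8)
  truth <- species_truth("sp", "clim1", optimum = 0.5, breadth = 0.2)
  expect_equal(nrow(simulate_occurrences(st, truth, 0)), 0)

  # occupancy confined to a single cell: all records at that cell centre
  one <- species_truth("sp", "clim1", optimum = 0.5, breadth = 0.2,
                       range = study_area("one", 3, 4, 3, 4))
  occ <- simulate_occurrences(st, one, 1, seed = 4)
  expect_equal(nrow(occ), 1)
  expect_equal(c(occ$x, occ$y), c(3.5, 3.5))
  expect_error(simulate_occurrences(st, one, 2, seed = 4),
               "positive occupancy")
})

test_that("occurrence mean environment matches the occupancy-weighted oracle", {
  cfg <- landscape_config(nrow = 60, ncol = 60, n_climate = 2,
                          n_landcover = 2, gradient = c(0.05, 0), seed = 31)
  st <- generate_environment(cfg)
  truth <- species_truth("sp", "clim1", optimum = 0.4, breadth = 0.3)
  occ <- simulate_occurrences(st, truth, 300, seed = 7)
  env_occ <- rs_extract(st, occ[, c("x", "y")], "clim1")
  p <- occupancy_probability(st, truth)
  oracle <- sum(p * rs_values(st, "clim1")[, 1]) / sum(p)
  expect_lt(abs(mean(env_occ) - oracle), 0.1 * 0.3)
  # at most one record per cell
  expect_equal(anyDuplicated(rs_cell(st, occ[, c("x", "y")])), 0L)
  # records concentrate where occupancy is high
  expect_gt(mean(p[rs_cell(st, occ[, c("x", "y")])]), 2 * mean(p))
})

test_that("analytic truth overlap behaves at its fixed points", {
  a <- species_truth("a", c("e1", "e2", "e3"), c(0, 0, 0), c(1, 1, 1))
  same <- truth_overlap(a, a, seed = 2)
  expect_equal(same$K, 1)
  expect_equal(same$OI, 1)
  far <- species_truth("b", c("e1", "e2", "e3"), c(100, 0, 0), c(1, 1, 1))
  expect_equal(truth_overlap(a, far, seed = 2)$I, 0)
  # closed-form 95% highest-density ball volume for a standard 3-D normal
  expect_equal(same$V1, (4 / 3) * pi * stats::qchisq(0.95, 3)^1.5,
               tolerance = 1e-10)
  # symmetry: swapping arguments swaps volumes, leaves K and OI unchanged
  b <- species_truth("b", c("e1", "e2", "e3"), c(1, 0.5, 0), c(2, 1, 0.5))
  ab <- truth_overlap(a, b, seed = 5)
  ba <- truth_overlap(b, a, seed = 5)
  expect_equal(ab$V1, ba$V2)
  expect_equal(ab$K, ba$K, tolerance = 0.02)
  expect_equal(ab$OI, ba$OI, tolerance = 0.02)
  mism <- species_truth("c", c("e1", "e2"), c(0, 0), c(1, 1))
  expect_error(truth_overlap(a, mism), "dimensionality")
})

test_that("occurrences and configs round-trip through their text formats", {
  st <- tiny_stack(6, 6)
  truth <- species_truth("sp", "clim1", 0.5, 0.3)
  occ <- assign_areas(simulate_occurrences(st, truth, 5, seed = 1),
                      list(zone = study_area("zone", 0, 3, 0, 3)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, f)
  back <- utils::read.csv(f)
  expect_equal(back$x, occ$x)
  expect_equal(names(back), c("species", "x", "y", "area"))

  g <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(st, "clim1", g)
  rt <- read_esri_ascii(g, "clim1")
  expect_equal(rt$layers$clim1, st$layers$clim1, tolerance = 1e-8)
  expect_equal(rt$xmin, st$xmin)

  y <- withr::local_tempfile(fileext = ".yml")
  cfg <- landscape_config(nrow = 10, ncol = 10, seed = 2)
  write_landscape_config(cfg, y, truths = list(sp = truth))
  parsed <- yaml::read_yaml(y)
  expect_equal(parsed$landscape$nrow, 10)
  expect_equal(parsed$species$sp$id, "sp")
})
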