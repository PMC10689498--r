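# Kernel-density hypervolumes: bandwidths, volume estimation, overlap
# indices and permutation randomisation.

test_that("Silverman bandwidths match the closed form", {
  x <- matrix(scale(rnorm(100)), ncol = 1)  # sd exactly 1
  expect_equal(silverman_bandwidth(x), (4 / (3 * 100))^(1 / 5),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal((4 / 300)^(1 / 5), 0.4216846, tolerance = 1e-6)

  set.seed(1)
  y <- matrix(rnorm(150), ncol = 3)
  # scaling the cloud scales the bandwidths by the same factor
  expect_equal(silverman_bandwidth(3.7 * y), 3.7 * silverman_bandwidth(y))

  # d = 3, n = 50, per-axis sd (1, 2, 0.5): constant (4/250)^(1/7)
  z <- matrix(rnorm(150), 50, 3)
  z <- sweep(sweep(z, 2, apply(z, 2, sd), "/"), 2, c(1, 2, 0.5), "*")
  const <- (4 / ((3 + 2) * 50))^(1 / (3 + 4))
  expect_equal(const, 0.5539183, tolerance = 1e-6)
  expect_equal(unname(silverman_bandwidth(z)), const * c(1, 2, 0.5),
               tolerance = 1e-9)

  expect_error(silverman_bandwidth(matrix(1, 5, 2)), "zero-variance")
  expect_error(silverman_bandwidth(matrix(1, 1, 2)), "at least 2")
})

test_that("volume estimation is deterministic, monotone in mass and stable across seeds", {
  x <- gaussian_scores(500, 3, seed = 2)
  h1 <- build_hypervolume(x, seed = 42)
  h2 <- build_hypervolume(x, seed = 42)
  expect_identical(h1$volume, h2$volume)
  expect_identical(h1$random_points, h2$random_points)

  h80 <- build_hypervolume(x, quantile = 0.80, seed = 42)
  expect_gt(h1$volume, h80$volume)

  # every representative point carries density >= the threshold
  expect_true(all(contactniche:::hv_density(h1, h1$random_points) >=
                    h1$threshold))

  # MC consistency: volume sd across 10 seeds below 3% of the mean
  vs <- vapply(1:10, function(s) build_hypervolume(x, seed = s)$volume,
               numeric(1))
  expect_lt(stats::sd(vs) / mean(vs), 0.03)

  expect_error(build_hypervolume(x, quantile = 1.2), "quantile")
  expect_error(build_hypervolume(matrix(1, 10, 3)), "zero-variance")
  expect_error(build_hypervolume(x[1:3, ]), "d \\+ 1")
})

test_that("overlap of a hypervolume with itself is exact and disjoint clouds do not intersect", {
  x <- gaussian_scores(300, 3, seed = 3)
  h <- build_hypervolume(x, seed = 1)
  self <- pairwise_overlap(h, h)
  expect_equal(self$K, 1)
  expect_equal(self$OI, 1)
  expect_equal(self$I, h$volume)

  far <- build_hypervolume(x + 50 * max(h$bandwidth), seed = 2)
  disj <- pairwise_overlap(h, far)
  expect_equal(disj$I, 0)
  expect_equal(disj$K, 0)

  expect_error(pairwise_overlap(h, build_hypervolume(x[, 1:2], seed = 1)),
               "dimensionality")
})

test_that("overlap is symmetric up to the V1/V2 swap", {
  a <- build_hypervolume(gaussian_scores(250, 3, seed = 4), seed = 1)
  b <- build_hypervolume(gaussian_scores(250, 3, shift = 1, seed = 5), seed = 2)
  ab <- pairwise_overlap(a, b)
  ba <- pairwise_overlap(b, a)
  expect_equal(ab$V1, ba$V2)
  expect_equal(ab$V2, ba$V1)
  expect_identical(ab$I, ba$I)
  expect_identical(ab$K, ba$K)
  expect_identical(ab$OI, ba$OI)
})

test_that("intersection of offset uniform cubes matches a dense-grid integration oracle", {
  set.seed(6)
  n <- 200
  A <- matrix(runif(n * 3), n, 3)
  B <- matrix(runif(n * 3), n, 3)
  B[, 1] <- B[, 1] + 0.5
  ha <- build_hypervolume(A, seed = 1)
  hb <- build_hypervolume(B, seed = 2)
  I_pkg <- pairwise_overlap(ha, hb)$I

  # independent oracle: Riemann sum of the two thresholded KDEs in pure R
  step <- 0.06
  gx <- seq(-0.45, 1.95, by = step)
  grid <- as.matrix(expand.grid(x = gx, y = gx, z = gx))
  kde_r <- function(g, pts, bw) {
    f <- numeric(nrow(g))
    for (i in seq_len(nrow(pts)))
      f <- f + dnorm(g[, 1], pts[i, 1], bw[1]) *
        dnorm(g[, 2], pts[i, 2], bw[2]) * dnorm(g[, 3], pts[i, 3], bw[3])
    f / nrow(pts)
  }
  fa <- kde_r(grid, A, ha$bandwidth)
  fb <- kde_r(grid, B, hb$bandwidth)
  I_oracle <- step^3 * sum(fa >= ha$threshold & fb >= hb$threshold)
  expect_lt(abs(I_pkg - I_oracle) / I_oracle, 0.2)
})

test_that("overlap indices reproduce published-style arithmetic and reject bad triples", {
  # volumes/intersections with known 3-dp index values
  expect_lt(abs(sorensen_index(22.677, 15.517, 11.451) - 0.601), 0.003)
  expect_lt(abs(overlap_index(22.677, 15.517, 11.451) - 0.739), 0.002)
  expect_lt(abs(sorensen_index(4.545, 3.812, 0.265) - 0.065), 0.003)
  expect_lt(abs(overlap_index(1.035, 1.540, 0.885) - 0.855), 0.002)
  expect_equal(sorensen_index(5, 5, 5), 1)
  expect_equal(overlap_index(7, 7, 0), 0)
  expect_error(sorensen_index(2, 3, 2.5), "smaller volume")
  expect_error(overlap_index(-1, 3, 0.5), "positive")
})

test_that("overlap_result enforces its invariants and feeds the report table", {
  r <- overlap_result(2, 1, 0.5, pK = 0.01, pOI = 0.2, n_perm = 99)
  expect_true(r$K <= r$OI)
  expect_error(overlap_result(2, 1, 1.5), "smaller volume")
  tab <- overlap_table(list("A versus B|climatic" = r))
  expect_equal(tab$comparison, "A versus B")
  expect_equal(tab$space, "climatic")
  expect_true(tab$signif)  # pK < 0.05
  f <- withr::local_tempfile(fileext = ".csv")
  write_overlap_table(tab, f)
  expect_equal(utils::read.csv(f)$K, r$K)
})

test_that("permutation test hits its fixed points", {
  # disjoint clouds: observed overlap 0 is minimal, p = 1/(n_perm + 1)
  a <- gaussian_scores(40, 3, seed = 7)
  b <- gaussian_scores(40, 3, shift = 60, seed = 8)
  pt <- permutation_overlap_test(a, b, n_perm = 19, seed = 1,
                                 n_mc = 1500, n_uniform = 150)
  expect_equal(pt$observed, 0)
  expect_equal(pt$p.value, 1 / 20)

  # identical point sets: the observed statistic sits inside the null support
  # (the pooled relabellings are near-copies, so the band is narrow)
  x <- gaussian_scores(30, 3, seed = 9)
  pt2 <- permutation_overlap_test(x, x, n_perm = 19, seed = 2,
                                  n_mc = 1500, n_uniform = 150)
  expect_gte(pt2$observed, min(pt2$null) - 0.05)
  expect_lte(pt2$observed, max(pt2$null) + 0.1)
  expect_gt(pt2$p.value, 0.05)

  # two-sided p doubles the smaller tail: for the disjoint clouds the lower
  # tail is minimal, so the two-sided p is exactly twice the one-sided one
  pt3 <- permutation_overlap_test(a, b, n_perm = 19, seed = 1,
                                  n_mc = 1500, n_uniform = 150,
                                  alternative = "two.sided")
  expect_equal(pt3$p.value, 2 * pt$p.value)
})

test_that("background hypervolumes are built from seeded area subsamples", {
  st <- tiny_stack(30, 30)
  m <- fit_pca(rs_values(st) + matrix(rnorm(1800, sd = 0.05), ncol = 2))
  area <- study_area("z", 0, 15, 0, 15)
  bg1 <- background_hypervolume(st, area, m, n = 100, k = 2, seed = 3,
                                n_mc = 1500, n_uniform = 100)
  bg2 <- background_hypervolume(st, area, m, n = 100, k = 2, seed = 3,
                                n_mc = 1500, n_uniform = 100)
  expect_identical(bg1$hypervolume$volume, bg2$hypervolume$volume)
  expect_equal(nrow(bg1$scores), 100)
})
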