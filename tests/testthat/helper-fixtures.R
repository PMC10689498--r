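# Fixtures built in code: small grids, score clouds and a reduced study
# configuration reused across test files.

# A tiny stack with one linear layer and one constant-ish layer.
tiny_stack <- function(nr = 10, nc = 12, cellsize = 1) {
  i <- rep.int(seq_len(nr), nc)
  j <- rep(seq_len(nc), each = nr)
  x <- (j - 0.5) * cellsize
  y <- (i - 0.5) * cellsize
  raster_stack(list(clim1 = matrix(x / nc, nr, nc),
                    clim2 = matrix(y / nr, nr, nc)),
               cellsize = cellsize)
}

# Multivariate normal scores with optional mean shift.
gaussian_scores <- function(n, d = 3, shift = 0, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d) + shift
}

# Single-layer stack from a function of cell-centre coordinates.
field_stack <- function(nr, nc, f, name = "p", cellsize = 1) {
  i <- rep.int(seq_len(nr), nc)
  j <- rep(seq_len(nc), each = nr)
  v <- f((j - 0.5) * cellsize, (i - 0.5) * cellsize)
  raster_stack(stats::setNames(list(matrix(v, nr, nc)), name),
               cellsize = cellsize)
}

# Reduced hypervolume settings used where only structure or direction is
# under test (Monte-Carlo sizes are resolution, not study conditions).
fast_hv <- list(n_perm = 2, n_mc = 2000, n_uniform = 200, n_background = 300)
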