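test_that("Delaunay summary agrees with simplex re-enumeration oracle", {
  set.seed(30)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    pts <- matrix(runif(3 * n), n, 3)
    ts <- delaunay_summary(pts, muscle_volume = 1)
    oracle <- brute_tess_stats(pts, ts$simplices)
    expect_equal(ts$mean_edge_length, oracle$mean_edge, tolerance = 1e-9)
    expect_equal(ts$mean_tet_volume, oracle$mean_vol, tolerance = 1e-9)
    expect_equal(ts$n_edges, oracle$n_edges)
  }
})

test_that("unit-cube corners tessellate consistently with the edge oracle", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  ts <- delaunay_summary(cube, muscle_volume = 1)
  oracle <- brute_tess_stats(cube, ts$simplices)
  expect_equal(ts$mean_edge_length, oracle$mean_edge, tolerance = 1e-12)
  # any valid triangulation of the cube fills its volume exactly
  expect_equal(sum(ts$tet_volumes), 1, tolerance = 1e-9)
})

test_that("tessellation metrics are scale equivariant", {
  set.seed(31)
  pts <- matrix(runif(90), 30, 3)
  a <- delaunay_summary(pts, muscle_volume = 1)
  b <- delaunay_summary(pts * 2, muscle_volume = 8)
  expect_equal(b$mean_edge_length, 2 * a$mean_edge_length, tolerance = 1e-12)
  expect_equal(b$mean_tet_volume, 8 * a$mean_tet_volume, tolerance = 1e-12)
  # normalisation removes the scale entirely
  expect_equal(b$normalized_mean_edge, a$normalized_mean_edge, tolerance = 1e-12)
  expect_equal(b$normalized_mean_volume, a$normalized_mean_volume,
               tolerance = 1e-12)
})

test_that("degenerate voxel-grid clouds are handled by jitter", {
  g <- as.matrix(expand.grid(1:4, 1:4, 1:3))
  ts <- delaunay_summary(g, muscle_volume = 36)
  expect_equal(sum(ts$tet_volumes), 3 * 3 * 2, tolerance = 1e-6)
  expect_error(delaunay_summary(matrix(runif(12), 4, 3), muscle_volume = 1),
               "at least 5")
})

test_that("Ripley K matches direct pair counting", {
  # two points at distance 1 in a domain of volume V: K(2) = V/2
  p2 <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(ripley_k(p2, radii = 2, volume = 12), 12 / 2)
  expect_equal(ripley_k(p2, radii = 0.5, volume = 12), 0)
  set.seed(32)
  for (i in 1:5) {
    n <- sample(5:50, 1)
    pts <- matrix(runif(3 * n), n, 3)
    radii <- seq(0.05, 0.8, by = 0.05)
    expect_equal(ripley_k(pts, radii, volume = 1),
                 brute_ripley_k(pts, radii, 1), tolerance = 1e-9)
  }
  expect_error(ripley_k(p2, radii = c(2, 1), volume = 1), "increasing")
})

test_that("K is non-decreasing in r and CSR expectation is the 4/3 pi r^3 law", {
  set.seed(33)
  pts <- matrix(runif(150), 50, 3)
  radii <- seq(0.05, 1, by = 0.05)
  K <- ripley_k(pts, radii, volume = 1)
  expect_true(all(diff(K) >= 0))
  expect_equal(csr_expectation(c(1, 2)), 4 / 3 * pi * c(1, 8))
})

test_that("CSR envelope is deterministic, ordered, and centred on CSR", {
  radii <- seq(0.05, 0.5, by = 0.05)
  dom <- list(lower = c(0, 0, 0), upper = c(1, 1, 1))
  e1 <- csr_envelope(50, dom, radii, n_sims = 99, seed = 5)
  e2 <- csr_envelope(50, dom, radii, n_sims = 99, seed = 5)
  expect_identical(e1, e2)
  expect_true(all(e1$low <= e1$high))
  # at radii small relative to the box, where the uncorrected K is nearly
  # unbiased, the envelope brackets the closed-form CSR expectation
  small <- radii <= 0.15
  expect_true(all(e1$low[small] <= csr_expectation(radii)[small]))
  expect_true(all(e1$high[small] >= csr_expectation(radii)[small]))
  # at all radii it brackets the empirical CSR mean (edge bias included)
  e4 <- csr_envelope(50, dom, radii, n_sims = 199, seed = 99)
  expect_true(all(e1$low <= colMeans(e4$sims)))
  expect_true(all(e1$high >= colMeans(e4$sims)))
  # single simulation: degenerate envelope
  e3 <- expect_warning(csr_envelope(30, dom, radii, n_sims = 1, seed = 1),
                       "39")
  expect_equal(e3$low, e3$high)
})

test_that("L transform maps CSR to zero in both modes", {
  radii <- seq(0.1, 1, by = 0.1)
  Kcsr <- csr_expectation(radii)
  expect_equal(l_function(Kcsr, radii, "besag"), rep(0, 10), tolerance = 1e-12)
  expect_equal(l_function(Kcsr, radii, "standard3d"), rep(0, 10),
               tolerance = 1e-12)
  expect_equal(l_function(pi, 1, "besag", center = FALSE), 1)
  expect_equal(l_function(4 / 3 * pi, 1, "standard3d"), 0, tolerance = 1e-12)
  expect_error(l_function(-1, 1), "non-negative")
})

test_that("maximum clustering distance interpolates the down-crossing", {
  radii <- seq(1, 20, by = 0.5)
  csr <- csr_expectation(radii)
  # construct an envelope that crosses CSR exactly at r* = 17.5
  rstar <- 17.5
  env <- csr + (rstar - radii)
  expect_equal(as.numeric(max_clustering_distance(radii, env, csr)), rstar,
               tolerance = 1e-9)
  below <- csr - 1
  mcd0 <- max_clustering_distance(radii, below, csr)
  expect_equal(as.numeric(mcd0), 0)
  expect_equal(attr(mcd0, "flag"), "no detectable clustering")
  above <- csr + 1
  mcdc <- max_clustering_distance(radii, above, csr)
  expect_equal(as.numeric(mcdc), 20)
  expect_equal(attr(mcdc, "flag"), "censored at grid end")
})

test_that("clustered phantom clouds exceed the CSR envelope at small r", {
  set.seed(35)
  # tight Gaussian clumps in a unit box
  centers <- matrix(runif(15), 5, 3)
  pts <- do.call(rbind, lapply(1:5, function(i)
    matrix(rnorm(60, centers[i, ], 0.02), 20, 3, byrow = TRUE)))
  radii <- seq(0.02, 0.3, by = 0.02)
  K <- ripley_k(pts, radii, volume = 1)
  env <- csr_envelope(nrow(pts), list(lower = c(0, 0, 0), upper = c(1, 1, 1)),
                      radii, n_sims = 99, seed = 7)
  expect_true(all(K[radii <= 0.1] > env$high[radii <= 0.1]))
})
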