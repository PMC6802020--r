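test_that("density surface integrates to n with mass at the points", {
  g <- grid_raster(matrix(0, 32, 32), xmin = 0, ymax = 32, cellsize = 1)
  one <- occurrence_set(10.5, 10.5)
  d <- density_surface(one, g, bandwidth = 1)
  expect_equal(sum(d$values), 1, tolerance = 1e-9)
  peak <- which(d$values == max(d$values), arr.ind = TRUE)
  expect_identical(as.integer(peak), c(22L, 11L))  # row 22 = y in (10, 11]

  # two separated clusters give two local maxima at the cluster centers
  cl <- occurrence_set(c(rep(5.5, 20), rep(26.5, 20)) + rnorm(40, 0, 0.2),
                       c(rep(5.5, 20), rep(26.5, 20)) + rnorm(40, 0, 0.2))
  d2 <- density_surface(cl, g, bandwidth = 2)
  expect_equal(sum(d2$values), 40, tolerance = 1e-9)
  m <- d2$values
  p1 <- m[27, 6]; p2 <- m[6, 27]   # rows from top: y=5.5 -> row 27
  # both peaks dominate the two cluster-free corners
  empty_max <- max(m[1:10, 1:10], m[23:32, 23:32])
  expect_gt(p1, empty_max)
  expect_gt(p2, empty_max)

  expect_error(density_surface(one, g, bandwidth = 0), "positive")
})

test_that("Ripley L behaves under CSR and extreme clustering", {
  # CSR points stay inside the 99-simulation envelope for >= 95% of radii
  # in >= 18/20 seeds
  pass <- 0
  for (sd in 1:20) {
    set.seed(sd + 100)
    occ <- occurrence_set(runif(50), runif(50))
    lc <- ripley_l(occ, window = c(0, 1, 0, 1), r_max = 0.2, n_r = 40,
                   n_sim = 99, seed = sd)
    inside <- mean(lc$l_obs >= lc$l_lower & lc$l_obs <= lc$l_upper)
    if (inside >= 0.95) pass <- pass + 1
  }
  expect_gte(pass, 18)

  # all points (nearly) at one location: L - r above the envelope at all r
  set.seed(1)
  occ1 <- occurrence_set(0.5 + runif(30, 0, 1e-4), 0.5 + runif(30, 0, 1e-4))
  lc1 <- ripley_l(occ1, window = c(0, 1, 0, 1), r_max = 0.2, n_r = 20,
                  n_sim = 99, seed = 2)
  expect_true(all(lc1$l_obs > lc1$l_upper))

  # K (hence L) nondecreasing in r
  expect_true(all(diff(lc1$l_obs) >= -1e-12))

  expect_error(ripley_l(occ1, window = c(0, 1, 0, 1), r_max = 0.6),
               "half the shorter")
  expect_error(ripley_l(occurrence_set(runif(5), runif(5))), "at least 10")
})

# O(n^2) double-loop oracle for Moran's I
moran_brute <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0; s0 <- 0
  for (i in 1:n) for (j in 1:n) {
    num <- num + w[i, j] * z[i] * z[j]
    s0 <- s0 + w[i, j]
  }
  (n / s0) * num / sum(z^2)
}

test_that("Moran's I matches closed forms and the brute-force oracle", {
  # 2x2 checkerboard with rook weights: I = -1
  vals <- c(1, 0, 0, 1)  # column-major 2x2: perfect alternation
  w <- morans_weights_rook(2, 2)
  m <- morans_i(vals, w)
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_equal(m$expected, -1 / 3)

  expect_error(morans_i(rep(2, 9), morans_weights_rook(3, 3)),
               "nonzero variance")

  # brute-force agreement on random instances, both weight schemes
  for (sd in 1:5) {
    set.seed(sd)
    n_side <- sample(4:8, 1)
    vals <- rnorm(n_side^2)
    coords <- expand.grid(x = 1:n_side, y = 1:n_side)
    for (w in list(morans_weights_rook(n_side, n_side),
                   morans_weights_invdist(as.matrix(coords), cutoff = 3))) {
      expect_equal(morans_i(vals, w)$I, moran_brute(vals, w),
                   tolerance = 1e-10)
    }
  }

  # independent cross-check against ape's implementation
  skip_if_not_installed("ape")
  set.seed(7)
  vals <- rnorm(36)
  w <- morans_weights_invdist(as.matrix(expand.grid(1:6, 1:6)))
  expect_equal(morans_i(vals, w)$I,
               ape::Moran.I(vals, w)$observed, tolerance = 1e-10)

  # permutation calibration: mean I over random permutations ~ -1/(n-1)
  set.seed(8)
  vals <- rnorm(100)
  w <- morans_weights_rook(10, 10)
  perm_I <- replicate(300, morans_i(sample(vals), w)$I)
  expect_equal(mean(perm_I), -1 / 99, tolerance = 0.012)
})

test_that("sparse grid weights equal their dense counterparts", {
  ws <- sdmflow:::sparse_grid_weights(5, 7, scheme = "rook")
  wd <- morans_weights_rook(5, 7)
  expect_equal(as.matrix(ws), wd, ignore_attr = TRUE)
  coords <- as.matrix(cell_center(
    grid_raster(matrix(0, 5, 7), xmin = 0, ymax = 5, cellsize = 1),
    rep(1:5, 7), rep(1:7, each = 5)))
  wi <- sdmflow:::sparse_grid_weights(5, 7, scheme = "invdist")
  wdi <- morans_weights_invdist(coords, cutoff = 3)
  expect_equal(as.matrix(wi), wdi, ignore_attr = TRUE)
})

test_that("resolution scan selects the finest admissible aggregation", {
  g <- grid_raster(matrix(0, 64, 64), xmin = 0, ymax = 64000,
                   cellsize = 1000)
  # spatially random occurrences: the finest resolution is admissible
  set.seed(2)
  occ <- occurrence_set(runif(300, 0, 64000), runif(300, 0, 64000))
  sc <- select_resolution(occ, g, resolutions = c(1, 5, 10, 20) * 1000,
                          seed = 3)
  expect_equal(sc$selected, 1000)
  expect_true(all(diff(sc$table$resolution) > 0))

  # clustered pattern (cluster scale ~8 cells) needs a coarser resolution
  set.seed(4)
  ctrs <- cbind(runif(6, 8000, 56000), runif(6, 8000, 56000))
  idx <- sample(1:6, 300, replace = TRUE)
  occ_cl <- occurrence_set(
    pmin(pmax(ctrs[idx, 1] + rnorm(300, 0, 4000), 1), 63999),
    pmin(pmax(ctrs[idx, 2] + rnorm(300, 0, 4000), 1), 63999))
  sc2 <- select_resolution(occ_cl, g, resolutions = c(1, 5, 10, 20) * 1000,
                           seed = 3)
  expect_gte(sc2$selected, 5000)

  expect_error(select_resolution(occ, g, resolutions = c(5000, 1000)),
               "increasing")
  expect_error(select_resolution(occ, g, resolutions = c(500, 1000)),
               "cell size")
})

test_that("replicate thinning keeps one point per cell until all covered", {
  g <- grid_raster(matrix(0, 16, 16), xmin = 0, ymax = 16, cellsize = 1)
  # all in distinct cells -> exactly one replicate
  occ <- occurrence_set(seq(0.5, 7.5), rep(0.5, 8))
  r1 <- thin_replicates(occ, g, resolution = 1, seed = 1)
  expect_identical(r1$n_replicates, 1L)

  # one cell with 5 points: at least 5 replicates (pigeonhole), and the
  # union of replicates recovers every original point
  occ5 <- occurrence_set(c(rep(0.5, 5) + runif(5, 0, 0.4), 2.5, 4.5),
                         c(rep(0.5, 5), 0.5, 0.5))
  r5 <- thin_replicates(occ5, g, resolution = 1, seed = 2)
  expect_gte(r5$n_replicates, 5L)
  expect_true(all(r5$coverage >= 1))
  for (rep_k in r5$replicates) {
    cells <- cell_at(g, rep_k$x, rep_k$y)$cell
    expect_false(any(duplicated(cells)))
  }

  # cycle mode: replicate count equals the max multiplicity
  rc <- thin_replicates(occ5, g, resolution = 1, mode = "cycle", seed = 3)
  expect_identical(rc$n_replicates, 5L)
  expect_true(all(rc$coverage >= 1))

  # replicate-count distribution matches the coupon-collector oracle
  counts <- vapply(1:60, function(sd)
    thin_replicates(occ5, g, resolution = 1, seed = sd)$n_replicates,
    integer(1))
  oracle <- vapply(1:2000, function(i) {
    seen <- logical(5); k <- 0
    while (!all(seen)) { k <- k + 1; seen[sample.int(5, 1)] <- TRUE }
    k
  }, numeric(1))
  expect_lt(abs(mean(counts) - mean(oracle)), 1.6)
})
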