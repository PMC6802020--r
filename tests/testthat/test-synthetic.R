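# Independent lag-1 Moran's I with rook neighbors, computed by direct
# summation over neighbor pairs (oracle for the random-field generator).
lag1_moran <- function(m) {
  z <- m - mean(m)
  num <- 0; s0 <- 0
  nr <- nrow(m); nc <- ncol(m)
  num <- sum(z[-1, ] * z[-nr, ]) * 2 + sum(z[, -1] * z[, -nc]) * 2
  s0 <- 2 * ((nr - 1) * nc + nr * (nc - 1))
  (length(m) / s0) * num / sum(z^2)
}

test_that("covariate fields honor the autocorrelation range", {
  s0 <- simulate_covariates(64, 64, autocorr_range = 0, seed = 3)
  expect_lt(abs(lag1_moran(s0$layers$cov1$values)), 0.1)

  s20 <- simulate_covariates(64, 64, autocorr_range = 20, seed = 3)
  expect_gt(lag1_moran(s20$layers$cov1$values), 0.5)

  # determinism and categorical layer structure
  s20b <- simulate_covariates(64, 64, autocorr_range = 20, seed = 3)
  expect_identical(s20$layers$cov1$values, s20b$layers$cov1$values)
  expect_true(all(s20$layers$landclass$values %in% 1:4))
  expect_gte(length(unique(as.vector(s20$layers$landclass$values))), 3)

  expect_error(simulate_covariates(8, 8), "16 x 16")
  expect_error(simulate_covariates(64, 64, autocorr_range = -1),
               "nonnegative")
})

test_that("virtual species suitability follows the logit-additive model", {
  s <- simulate_covariates(32, 32, seed = 1)
  vs0 <- build_virtual_species(s, list(), intercept = 0)
  expect_true(all(vs0$truth$values == 0.5))

  vs_neg <- build_virtual_species(s, list(), intercept = -20)
  expect_true(all(vs_neg$truth$values < 1e-6))

  vs_lin <- build_virtual_species(
    s, list(list(covariate = "cov1", type = "linear", slope = 2)))
  # monotone in cov1: suitability ordering matches covariate ordering
  o <- order(as.vector(s$layers$cov1$values))
  expect_true(all(diff(as.vector(vs_lin$truth$values)[o]) >= 0))

  expect_error(build_virtual_species(
    s, list(list(covariate = "nope", type = "linear", slope = 1))),
    "unknown covariate")
})

vs_no_support <- function(s) {
  vs <- build_virtual_species(s, list(), intercept = 0)
  vs$truth$values[] <- 0
  vs
}

test_that("occurrence sampling follows effort x suitability weights", {
  s <- simulate_covariates(64, 64, seed = 2)
  g <- s$layers[[1]]
  flat <- build_virtual_species(s, list(), intercept = 20) # truth ~ 1

  # uniform effort, flat truth: quadrat chi-square non-significant at
  # alpha = 0.01 in >= 18/20 seeds
  eff_u <- effort_surface(g, "uniform")
  pass <- 0
  for (sd in 1:20) {
    occ <- sample_occurrences(flat, eff_u, 400, seed = sd)
    qx <- cut(occ$x, seq(0, 64000, length.out = 5), include.lowest = TRUE)
    qy <- cut(occ$y, seq(0, 64000, length.out = 5), include.lowest = TRUE)
    cnt <- as.vector(table(qx, qy))
    p <- chisq.test(cnt)$p.value
    if (p > 0.01) pass <- pass + 1
  }
  expect_gte(pass, 18)

  # effort concentrated 1000:1 in one quadrant -> >= 95% of points there
  effm <- matrix(1, 64, 64); effm[1:32, 1:32] <- 1000
  eff_q <- grid_raster(effm / sum(effm), xmin = 0, ymax = 64000,
                       cellsize = 1000)
  occ_q <- sample_occurrences(flat, eff_q, 500, seed = 4)
  in_q <- mean(occ_q$x < 32000 & occ_q$y > 32000)
  expect_gte(in_q, 0.95)

  # binary truth mask with detection 1: all points inside the mask
  maskm <- matrix(0, 64, 64); maskm[, 1:16] <- 1
  lp <- grid_raster(ifelse(maskm == 1, 40, -40), xmin = 0, ymax = 64000,
                    cellsize = 1000)
  vs_mask <- build_virtual_species(
    raster_stack(m = lp), list(list(covariate = "m", type = "linear",
                                    slope = 1)))
  occ_m <- sample_occurrences(vs_mask, eff_u, 200, detection = 1, seed = 5)
  expect_true(all(occ_m$x < 16000))

  expect_error(sample_occurrences(vs_no_support(s), eff_u, 10),
               "no support")
})

test_that("region partitions are exhaustive, disjoint and contiguous", {
  one <- make_region_partition(20, 20, 1, seed = 1)
  expect_true(all(one$values == 1))

  reg <- make_region_partition(64, 64, 4, cellsize = 1, seed = 9)
  ids <- sort(unique(as.vector(reg$values)))
  expect_identical(ids, as.numeric(1:4))
  expect_false(anyNA(reg$values))

  # contiguity oracle: flood fill from one cell of each region must reach
  # all cells of that region
  connected <- function(m, id) {
    cells <- which(m == id, arr.ind = TRUE)
    seen <- matrix(FALSE, nrow(m), ncol(m))
    queue <- list(cells[1, ])
    seen[cells[1, 1], cells[1, 2]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        r <- cur[1] + d[1]; c <- cur[2] + d[2]
        if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) &&
            !seen[r, c] && m[r, c] == id) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
    sum(seen) == nrow(cells)
  }
  for (id in 1:4) expect_true(connected(reg$values, id))

  expect_error(make_region_partition(16, 16, 300), "more regions")
})

test_that("expert and citizen presets produce distinct, complementary biases", {
  w <- small_world(seed = 11, n_rows = 64, n_cols = 64)
  g <- w$stack$layers[[1]]
  dens_e <- density_surface(w$expert, g)
  dens_c <- density_surface(w$citizen, g)
  rho <- function(a, b) cor(as.vector(a$values), as.vector(b$values),
                            method = "spearman")
  # each density tracks its own effort better than the other scenario's
  expect_gt(rho(dens_e, w$effort_expert), rho(dens_e, w$effort_citizen))
  expect_gt(rho(dens_c, w$effort_citizen), rho(dens_c, w$effort_expert))
  expect_gt(rho(dens_e, w$effort_expert), 0)
  expect_gt(rho(dens_c, w$effort_citizen), 0)

  # merging covers strictly more 20-cell blocks than either source alone
  blocks <- function(occ) {
    bg <- grid_raster(matrix(0, 4, 4), xmin = 0, ymax = 64000,
                      cellsize = 20000)
    unique(cell_at(bg, occ$x, occ$y)$cell)
  }
  merged <- merge_datasets(w$expert, w$citizen, g)
  expect_gt(length(blocks(merged)), length(blocks(w$expert)))
  expect_gt(length(blocks(merged)), length(blocks(w$citizen)))
})
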