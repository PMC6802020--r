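# Shared in-code fixtures: a small landscape with the default virtual
# species, and generators for simple point patterns and training tables.

small_world <- function(seed = 42, n_rows = 48, n_cols = 48) {
  simulate_study(n_rows = n_rows, n_cols = n_cols, n_expert = 150,
                 n_citizen = 150, n_regions = 4, seed = seed)
}

# unbiased training data from a given world
unbiased_table <- function(world, n = 300, seed = 5, multiplier = 4) {
  g <- world$stack$layers[[1]]
  occ <- sample_occurrences(world$species, effort_surface(g, "uniform"),
                            n, seed = seed)
  pa <- generate_random(occ, g, multiplier = multiplier, seed = seed + 1)
  build_training_table(occ, pa, world$stack)
}

# a tiny raster with known values
tiny_raster <- function(nr = 10, nc = 10, cellsize = 1, seed = 1) {
  set.seed(seed)
  grid_raster(matrix(rnorm(nr * nc), nr), xmin = 0, ymax = nr * cellsize,
              cellsize = cellsize)
}

# Bernoulli data from a known quadratic-logistic truth over 2 covariates
quad_logistic_data <- function(n, beta = c(0.5, 1.5, -1, 0.8, -0.6),
                               seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  lp <- beta[1] + beta[2] * x1 + beta[3] * x1^2 + beta[4] * x2 +
    beta[5] * x2^2
  y <- rbinom(n, 1, plogis(lp))
  tab <- tibble::tibble(cov_a = x1, cov_b = x2, response = y)
  attr(tab, "covariates") <- c("cov_a", "cov_b")
  tab
}
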