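#' Simulate spatially autocorrelated covariate rasters
#'
#' Generates `k_continuous` stationary Gaussian random fields (white noise
#' smoothed with a Gaussian kernel whose scale is set from
#' `autocorr_range`, then standardized to mean 0, sd 1) plus one
#' categorical layer (`landclass`) obtained by thresholding an extra field
#' into `n_classes` equal-frequency classes.
#'
#' @param n_rows,n_cols grid dimensions (at least 16 x 16).
#' @param k_continuous number of continuous covariates (>= 2).
#' @param autocorr_range correlation range in cells; 0 gives white noise.
#' @param n_classes number of categories for the categorical layer (>= 3).
#' @param cellsize cell side in map units (default 1000 = 1-km cells).
#' @param seed RNG seed.
#' @return A [raster_stack] with layers `cov1..covK` and `landclass`.
#' @export
simulate_covariates <- function(n_rows, n_cols, k_continuous = 4,
                                autocorr_range = 10, n_classes = 4,
                                cellsize = 1000, seed = 1) {
  if (n_rows < 16 || n_cols < 16) stop("grid must be at least 16 x 16",
                                       call. = FALSE)
  if (k_continuous < 2) stop("need at least 2 continuous covariates",
                             call. = FALSE)
  if (autocorr_range < 0) stop("autocorr_range must be nonnegative",
                               call. = FALSE)
  set.seed(seed)
  sd_cells <- autocorr_range / 2
  field <- function() {
    f <- gaussian_blur(matrix(stats::rnorm(n_rows * n_cols), n_rows), sd_cells)
    (f - mean(f)) / stats::sd(f)
  }
  layers <- list()
  for (i in seq_len(k_continuous)) {
    layers[[paste0("cov", i)]] <- grid_raster(
      field(), xmin = 0, ymax = n_rows * cellsize, cellsize = cellsize)
  }
  extra <- field()
  cuts <- stats::quantile(extra, probs = seq(0, 1, length.out = n_classes + 1))
  cls <- matrix(as.numeric(cut(extra, cuts, include.lowest = TRUE,
                               labels = FALSE)), n_rows)
  layers$landclass <- grid_raster(cls, xmin = 0, ymax = n_rows * cellsize,
                                  cellsize = cellsize, categorical = TRUE)
  raster_stack(layers)
}

#' Build a virtual species with known suitability truth
#'
#' Response curves combine additively on the logit scale:
#' `suitability = plogis(intercept + sum of curve contributions)`.
#' Supported curve types: `"gaussian"` (unimodal,
#' `height * exp(-(x - mu)^2 / (2 sd^2))`), `"logistic"` (monotone,
#' `height * plogis((x - mu) / scale)`), `"linear"` (`slope * x`), and
#' `"categorical"` (named per-class contribution vector).
#'
#' @param stack a [raster_stack].
#' @param curves list of curve definitions; each is a list with elements
#'   `covariate`, `type`, and the type's parameters (`mu`, `sd`, `height`,
#'   `scale`, `slope`, `levels`).
#' @param intercept logit-scale intercept.
#' @return Object of class `virtual_species`: list with `curves`,
#'   `intercept`, and `truth` (a [grid_raster] of suitability in \[0, 1\]).
#' @export
build_virtual_species <- function(stack, curves, intercept = 0) {
  g0 <- stack$layers[[1]]
  lp <- matrix(intercept, nrow(g0$values), ncol(g0$values))
  for (cv in curves) {
    nm <- cv$covariate
    if (!nm %in% names(stack$layers)) {
      stop("curve references unknown covariate: ", nm, call. = FALSE)
    }
    x <- stack$layers[[nm]]$values
    contrib <- switch(cv$type,
      gaussian = cv$height * exp(-(x - cv$mu)^2 / (2 * cv$sd^2)),
      logistic = cv$height * stats::plogis((x - cv$mu) / cv$scale),
      linear = cv$slope * x,
      categorical = {
        lv <- cv$levels
        out <- matrix(0, nrow(x), ncol(x))
        for (cls in names(lv)) out[x == as.numeric(cls)] <- lv[[cls]]
        out
      },
      stop("unknown curve type: ", cv$type, call. = FALSE)
    )
    lp <- lp + contrib
  }
  truth <- grid_raster(stats::plogis(lp), xmin = g0$xmin, ymax = g0$ymax,
                       cellsize = g0$cellsize, crs = g0$crs)
  structure(list(curves = curves, intercept = intercept, truth = truth),
            class = "virtual_species")
}

#' Default virtual species
#'
#' Two unimodal (Gaussian) responses, one monotone (logistic) response,
#' and one categorical response — the mix of shapes typical of
#' temperature, precipitation, distance-to-resource and land-class
#' drivers in terrestrial vertebrate niche models.
#'
#' @param stack a stack from [simulate_covariates()] (needs `cov1..cov3`
#'   and `landclass`).
#' @param intercept logit intercept controlling overall prevalence.
#' @return A `virtual_species`.
#' @export
default_virtual_species <- function(stack, intercept = -5) {
  build_virtual_species(stack, list(
    list(covariate = "cov1", type = "gaussian", mu = 0.5, sd = 0.8, height = 4),
    list(covariate = "cov2", type = "gaussian", mu = -0.5, sd = 1.0, height = 3),
    list(covariate = "cov3", type = "logistic", mu = 0, scale = 0.5, height = 3),
    list(covariate = "landclass", type = "categorical",
         levels = list(`1` = -0.5, `2` = 0, `3` = 0.5, `4` = 1))
  ), intercept = intercept)
}

#' Sampling-effort surfaces for the two observer scenarios
#'
#' `"expert"` effort concentrates in a few clustered hotspots (long-running
#' field sites); `"citizen"` effort follows broad access corridors plus a
#' diffuse background (opportunistic reporting near travel routes).
#'
#' @param grid a [grid_raster] defining the geometry.
#' @param scenario `"expert"`, `"citizen"`, or `"uniform"`.
#' @param n_hotspots number of expert hotspots.
#' @param seed RNG seed.
#' @return A [grid_raster] of nonnegative effort summing to 1.
#' @export
effort_surface <- function(grid, scenario = c("expert", "citizen", "uniform"),
                           n_hotspots = 4, seed = 1) {
  scenario <- match.arg(scenario)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  set.seed(child_seed(seed, paste0("effort-", scenario)))
  rowc <- matrix(seq_len(nr), nr, nc)
  colc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  eff <- switch(scenario,
    uniform = matrix(1, nr, nc),
    expert = {
      e <- matrix(0.002, nr, nc)
      for (i in seq_len(n_hotspots)) {
        cr <- stats::runif(1, 0.15, 0.85) * nr
        cc <- stats::runif(1, 0.15, 0.85) * nc
        s <- stats::runif(1, 0.03, 0.06) * min(nr, nc)
        e <- e + exp(-((rowc - cr)^2 + (colc - cc)^2) / (2 * s^2))
      }
      e
    },
    citizen = {
      # two straight corridors (one ~horizontal, one ~vertical) with broad
      # falloff, over a smooth low-level background
      e <- matrix(0.05, nr, nc)
      r0 <- stats::runif(1, 0.25, 0.75) * nr
      c0 <- stats::runif(1, 0.25, 0.75) * nc
      w <- 0.08 * min(nr, nc)
      e <- e + exp(-(rowc - r0)^2 / (2 * w^2)) +
        exp(-(colc - c0)^2 / (2 * w^2))
      e
    })
  eff <- eff / sum(eff)
  grid_raster(eff, xmin = grid$xmin, ymax = grid$ymax,
              cellsize = grid$cellsize, crs = grid$crs)
}

#' Sample biased presence-only occurrence records
#'
#' Cells are drawn (with replacement — repeat visits happen) with
#' probability proportional to `effort x truth suitability x detection`;
#' each record is jittered uniformly within its cell.
#'
#' @param vs a `virtual_species`.
#' @param effort a [grid_raster] of sampling effort on the truth's grid.
#' @param n_points number of records to draw (>= 1).
#' @param detection per-visit detection probability in (0, 1].
#' @param source provenance label stored on the records.
#' @param date_range year range records are stamped with (uniform).
#' @param seed RNG seed.
#' @return An [occurrence_set] tibble of `n_points` records.
#' @export
sample_occurrences <- function(vs, effort, n_points, detection = 1,
                               source = "expert", date_range = c(1970, 2012),
                               seed = 1) {
  stopifnot(n_points >= 1, detection > 0, detection <= 1)
  truth <- vs$truth
  stop_if_grid_mismatch(truth, effort, "truth and effort")
  w <- as.vector(effort$values) * as.vector(truth$values) * detection
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("no support: effort x suitability is zero everywhere",
                        call. = FALSE)
  set.seed(seed)
  nr <- nrow(truth$values)
  cells <- sample.int(length(w), n_points, replace = TRUE, prob = w)
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  s <- truth$cellsize
  x <- truth$xmin + (col - 1L) * s + stats::runif(n_points) * s
  y <- truth$ymax - (row - 1L) * s - stats::runif(n_points) * s
  occurrence_set(x, y,
                 date = sample(seq(date_range[1], date_range[2]), n_points,
                               replace = TRUE),
                 source = source, crs = truth$crs)
}

#' Partition the grid into contiguous regions
#'
#' Voronoi tessellation of the grid around randomly placed region seeds
#' (Euclidean distance between cell centers, ties to the lower region id),
#' emulating physiographic divisions for out-of-region validation.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_regions number of regions (2..cells).
#' @param cellsize cell side in map units.
#' @param seed RNG seed.
#' @return A categorical [grid_raster] with region ids `1..n_regions`.
#' @export
make_region_partition <- function(n_rows, n_cols, n_regions, cellsize = 1000,
                                  seed = 1) {
  if (n_regions < 1) stop("n_regions must be >= 1", call. = FALSE)
  if (n_regions > n_rows * n_cols) {
    stop("more regions than grid cells", call. = FALSE)
  }
  set.seed(seed)
  seeds <- sample.int(n_rows * n_cols, n_regions)
  sr <- ((seeds - 1L) %% n_rows) + 1L
  sc <- ((seeds - 1L) %/% n_rows) + 1L
  rowc <- matrix(seq_len(n_rows), n_rows, n_cols)
  colc <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  best <- matrix(Inf, n_rows, n_cols)
  id <- matrix(1, n_rows, n_cols)
  for (k in seq_len(n_regions)) {
    d <- (rowc - sr[k])^2 + (colc - sc[k])^2
    upd <- d < best
    id[upd] <- k
    best[upd] <- d[upd]
  }
  grid_raster(id, xmin = 0, ymax = n_rows * cellsize, cellsize = cellsize,
              categorical = TRUE)
}

#' Simulate a complete study system
#'
#' Convenience wrapper producing the landscape, the default virtual
#' species, expert- and citizen-biased occurrence samples, and a region
#' partition — the study conditions every pipeline stage is exercised on.
#'
#' @param n_rows,n_cols grid size.
#' @param n_expert,n_citizen occurrence counts for the two scenarios.
#' @param n_regions regions in the partition.
#' @param autocorr_range covariate correlation range in cells.
#' @param seed RNG seed; all internal draws derive from it.
#' @return List with `stack`, `species`, `expert`, `citizen`,
#'   `effort_expert`, `effort_citizen`, `regions`.
#' @export
simulate_study <- function(n_rows = 64, n_cols = 64, n_expert = 300,
                           n_citizen = 300, n_regions = 6,
                           autocorr_range = 10, seed = 1) {
  stack <- simulate_covariates(n_rows, n_cols, k_continuous = 4,
                               autocorr_range = autocorr_range,
                               seed = child_seed(seed, "covariates"))
  vs <- default_virtual_species(stack)
  g0 <- stack$layers[[1]]
  eff_e <- effort_surface(g0, "expert", seed = child_seed(seed, "eff-e"))
  eff_c <- effort_surface(g0, "citizen", seed = child_seed(seed, "eff-c"))
  expert <- sample_occurrences(vs, eff_e, n_expert, source = "expert",
                               seed = child_seed(seed, "occ-e"))
  citizen <- sample_occurrences(vs, eff_c, n_citizen, source = "citizen",
                                seed = child_seed(seed, "occ-c"))
  regions <- make_region_partition(n_rows, n_cols, n_regions,
                                   cellsize = g0$cellsize,
                                   seed = child_seed(seed, "regions"))
  list(stack = stack, species = vs, expert = expert, citizen = citizen,
       effort_expert = eff_e, effort_citizen = eff_c, regions = regions)
}
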