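#' Sampling-effort density surface
#'
#' Gaussian kernel intensity of the occurrence pattern evaluated on the
#' covariate grid: per-cell counts smoothed with a Gaussian kernel of the
#' given bandwidth and renormalized so the surface integrates (sums) to
#' the number of input points.
#'
#' @param occ an [occurrence_set] with at least one point.
#' @param grid the covariate [grid_raster].
#' @param bandwidth kernel standard deviation in map units (default 5
#'   cells).
#' @return A [grid_raster] of nonnegative intensity; attribute
#'   `bandwidth` records the kernel scale.
#' @export
density_surface <- function(occ, grid, bandwidth = 5 * grid$cellsize) {
  if (nrow(occ) < 1) stop("need at least one point", call. = FALSE)
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  idx <- cell_at(grid, occ$x, occ$y)
  idx <- idx[!is.na(idx$cell), ]
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  counts <- matrix(0, nr, nc)
  tab <- table(idx$cell)
  counts[as.integer(names(tab))] <- as.integer(tab)
  sm <- gaussian_blur(counts, bandwidth / grid$cellsize)
  sm <- sm * (nrow(idx) / sum(sm))
  out <- grid_raster(sm, xmin = grid$xmin, ymax = grid$ymax,
                     cellsize = grid$cellsize, crs = grid$crs)
  attr(out, "bandwidth") <- bandwidth
  out
}

#' Ripley's L function with a CSR simulation envelope
#'
#' Edge-corrected L(r) = sqrt(K(r)/pi) of the point pattern on a
#' rectangular window, with a pointwise envelope from `n_sim` simulations
#' of complete spatial randomness (uniform points, same n). Values of
#' `l - r` above the envelope indicate clustering at that scale.
#'
#' @param occ an [occurrence_set] with >= 10 points.
#' @param window numeric `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   bounding box of the points.
#' @param r_max largest radius scanned; must be below half the shorter
#'   window side. Defaults to a quarter of the shorter side.
#' @param n_r number of radii.
#' @param n_sim number of CSR simulations for the envelope (>= 99 for the
#'   conventional 1% pointwise band).
#' @param seed RNG seed for the envelope simulations.
#' @return Tibble with columns `r`, `l_obs`, `l_lower`, `l_upper`,
#'   `l_csr_mean`.
#' @export
ripley_l <- function(occ, window = NULL, r_max = NULL, n_r = 50,
                     n_sim = 99, seed = 1) {
  if (nrow(occ) < 10) stop("need at least 10 points", call. = FALSE)
  if (is.null(window)) {
    window <- c(range(occ$x), range(occ$y))
  }
  short <- min(window[2] - window[1], window[4] - window[3])
  if (is.null(r_max)) r_max <- short / 4
  if (r_max >= short / 2) {
    stop("r_max must be below half the shorter window side", call. = FALSE)
  }
  set.seed(seed)
  spatial::ppregion(window[1], window[2], window[3], window[4])
  obs <- spatial::Kfn(list(x = occ$x, y = occ$y), fs = r_max, k = n_r)
  n <- nrow(occ)
  sims <- matrix(NA_real_, n_sim, n_r)
  for (s in seq_len(n_sim)) {
    px <- stats::runif(n, window[1], window[2])
    py <- stats::runif(n, window[3], window[4])
    sims[s, ] <- spatial::Kfn(list(x = px, y = py), fs = r_max, k = n_r)$y
  }
  tibble::tibble(
    r = obs$x, l_obs = obs$y,
    l_lower = apply(sims, 2, min),
    l_upper = apply(sims, 2, max),
    l_csr_mean = colMeans(sims)
  )
}

#' Spatial weight matrices for Moran's I
#'
#' `morans_weights_rook()` gives binary rook contiguity on a grid of
#' blocks; `morans_weights_invdist()` gives inverse Euclidean distance
#' between block centroids with a distance cutoff, optionally
#' row-standardized (the default scheme used by GIS global-Moran tools).
#'
#' @param coords two-column matrix of block centroid coordinates.
#' @param cutoff distance beyond which weights are zero.
#' @param row_standardize divide each row by its sum.
#' @return Square weight matrix with zero diagonal.
#' @export
morans_weights_invdist <- function(coords, cutoff = Inf,
                                   row_standardize = TRUE) {
  d <- as.matrix(stats::dist(coords))
  w <- ifelse(d > 0 & d <= cutoff, 1 / d, 0)
  if (row_standardize) {
    rs <- rowSums(w)
    w[rs > 0, ] <- w[rs > 0, ] / rs[rs > 0]
  }
  w
}

#' @param n_rows,n_cols block grid dimensions (row-major, row 1 on top).
#' @rdname morans_weights_invdist
#' @export
morans_weights_rook <- function(n_rows, n_cols) {
  n <- n_rows * n_cols
  w <- matrix(0, n, n)
  id <- function(r, c) r + (c - 1) * n_rows
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    if (r > 1) w[id(r, c), id(r - 1, c)] <- 1
    if (r < n_rows) w[id(r, c), id(r + 1, c)] <- 1
    if (c > 1) w[id(r, c), id(r, c - 1)] <- 1
    if (c < n_cols) w[id(r, c), id(r, c + 1)] <- 1
  }
  w
}

#' Global Moran's I
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the mean
#' deviations; expectation under no autocorrelation is `-1/(n-1)`; the
#' z-score uses the variance under the normality assumption.
#'
#' @param values numeric vector (>= 2 values, nonzero variance).
#' @param weights square spatial weight matrix, zero diagonal.
#' @return List with `I`, `expected`, `sd`, `z`, `p` (two-sided).
#' @export
morans_i <- function(values, weights) {
  n <- length(values)
  if (n < 2 || stats::var(values) == 0) {
    stop("Moran's I undefined: need >= 2 values with nonzero variance",
         call. = FALSE)
  }
  stopifnot(nrow(weights) == n, ncol(weights) == n)
  z <- values - mean(values)
  s0 <- sum(weights)
  I <- (n / s0) * as.numeric(Matrix::crossprod(z, weights %*% z)) / sum(z^2)
  e <- -1 / (n - 1)
  wt <- weights + Matrix::t(weights)
  s1 <- 0.5 * sum(wt * wt)
  s2 <- sum((Matrix::rowSums(weights) + Matrix::colSums(weights))^2)
  b2 <- n * sum(z^4) / (sum(z^2)^2)
  v <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
          b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - e^2
  sdv <- sqrt(max(v, 0))
  zscore <- (I - e) / sdv
  list(I = I, expected = e, sd = sdv, z = zscore,
       p = 2 * stats::pnorm(-abs(zscore)))
}

# Sparse spatial weights for a full block grid (row-major cell ids as used
# by cell_at): inverse distance with cutoff (in block widths) or rook
# contiguity; row-standardized for the inverse-distance scheme. Built from
# neighbor offsets so the memory cost is O(n x neighbors), not O(n^2).
sparse_grid_weights <- function(n_rows, n_cols, scheme = "invdist",
                                cutoff_blocks = 3) {
  offs <- expand.grid(dr = -cutoff_blocks:cutoff_blocks,
                      dc = -cutoff_blocks:cutoff_blocks)
  d <- sqrt(offs$dr^2 + offs$dc^2)
  keep <- if (scheme == "rook") d == 1 else d > 0 & d <= cutoff_blocks
  offs <- offs[keep, ]
  wts <- if (scheme == "rook") rep(1, nrow(offs)) else 1 / d[keep]
  rows <- rep(seq_len(n_rows), times = n_cols)
  cols <- rep(seq_len(n_cols), each = n_rows)
  ii <- jj <- ww <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    r2 <- rows + offs$dr[k]; c2 <- cols + offs$dc[k]
    ok <- r2 >= 1 & r2 <= n_rows & c2 >= 1 & c2 <= n_cols
    ii[[k]] <- which(ok)
    jj[[k]] <- r2[ok] + (c2[ok] - 1L) * n_rows
    ww[[k]] <- rep(wts[k], sum(ok))
  }
  w <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(n_rows * n_cols, n_rows * n_cols))
  if (scheme != "rook") {
    rs <- Matrix::rowSums(w)
    w <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% w
  }
  w
}

# Aggregate point counts to b x b blocks of the base grid; returns counts
# matrix (blocks) and block-centroid coordinates.
aggregate_counts <- function(occ, grid, block_cells) {
  nr <- ceiling(nrow(grid$values) / block_cells)
  nc <- ceiling(ncol(grid$values) / block_cells)
  bs <- block_cells * grid$cellsize
  bg <- grid_raster(matrix(0, nr, nc), xmin = grid$xmin, ymax = grid$ymax,
                    cellsize = bs)
  idx <- cell_at(bg, occ$x, occ$y)
  counts <- matrix(0, nr, nc)
  tab <- table(idx$cell[!is.na(idx$cell)])
  counts[as.integer(names(tab))] <- as.integer(tab)
  ctr <- cell_center(bg, rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  list(counts = counts, coords = cbind(ctr$x, ctr$y), block_grid = bg)
}

#' Scan aggregation resolutions for residual spatial autocorrelation
#'
#' At each candidate resolution the occurrences are aggregated to
#' per-block counts and global Moran's I is computed, alongside the same
#' statistic for random reference point sets (`reference_multiplier`
#' times as many points, uniform over the study area). The selected
#' resolution is the finest one at which the occurrence pattern's I is
#' not significantly above the random reference (one-sided z against the
#' reference replicates' distribution at `alpha`) — the coarsening that
#' controls autocorrelation while giving up the least spatial detail.
#'
#' @param occ an [occurrence_set].
#' @param grid the covariate [grid_raster].
#' @param resolutions block sizes to scan, in map units (each >= the grid
#'   cell size), strictly increasing.
#' @param reference_multiplier reference point count as a multiple of the
#'   occurrence count (default 10).
#' @param n_reference number of random reference replicates.
#' @param alpha significance level of the indistinguishability test.
#' @param scheme weight scheme: `"invdist"` (row-standardized inverse
#'   distance, cutoff 3 block widths) or `"rook"`.
#' @param seed RNG seed.
#' @return List of class `resolution_scan`: `table` (tibble with per-
#'   resolution `I_occ`, `z_occ`, `I_ref_mean`, `I_ref_sd`, `z_diff`,
#'   `admissible`) and `selected` (map units, `NA` if none admissible).
#' @export
select_resolution <- function(occ, grid, resolutions,
                              reference_multiplier = 10, n_reference = 19,
                              alpha = 0.05, scheme = c("invdist", "rook"),
                              seed = 1) {
  scheme <- match.arg(scheme)
  if (is.unsorted(resolutions, strictly = TRUE)) {
    stop("resolutions must be strictly increasing", call. = FALSE)
  }
  if (any(resolutions < grid$cellsize)) {
    stop("resolutions must be >= the grid cell size", call. = FALSE)
  }
  set.seed(seed)
  ext <- grid_extent(grid)
  n <- nrow(occ)
  rows <- list()
  for (res in resolutions) {
    bc <- max(1L, round(res / grid$cellsize))
    agg <- aggregate_counts(occ, grid, bc)
    w <- sparse_grid_weights(nrow(agg$counts), ncol(agg$counts),
                             scheme = scheme)
    if (stats::var(as.vector(agg$counts)) == 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        resolution = res, I_occ = NA_real_, z_occ = NA_real_,
        I_ref_mean = NA_real_, I_ref_sd = NA_real_, z_diff = NA_real_,
        admissible = NA)
      next
    }
    mo <- morans_i(as.vector(agg$counts), w)
    refI <- vapply(seq_len(n_reference), function(i) {
      rx <- stats::runif(reference_multiplier * n, ext["xmin"], ext["xmax"])
      ry <- stats::runif(reference_multiplier * n, ext["ymin"], ext["ymax"])
      ra <- aggregate_counts(occurrence_set(rx, ry), grid, bc)
      if (stats::var(as.vector(ra$counts)) == 0) return(NA_real_)
      morans_i(as.vector(ra$counts), w)$I
    }, numeric(1))
    refI <- refI[!is.na(refI)]
    z_diff <- (mo$I - mean(refI)) / max(stats::sd(refI), 1e-12)
    rows[[length(rows) + 1]] <- tibble::tibble(
      resolution = res, I_occ = mo$I, z_occ = mo$z,
      I_ref_mean = mean(refI), I_ref_sd = stats::sd(refI), z_diff = z_diff,
      admissible = z_diff <= stats::qnorm(1 - alpha))
  }
  tab <- dplyr::bind_rows(rows)
  adm <- tab$resolution[which(tab$admissible)]
  if (!length(adm)) {
    warning("no scanned resolution controls the autocorrelation; no selection")
    sel <- NA_real_
  } else sel <- min(adm)
  structure(list(table = tab, selected = sel), class = "resolution_scan")
}

#' @export
print.resolution_scan <- function(x, ...) {
  cat("<resolution_scan> selected:", x$selected, "\n")
  print(x$table)
  invisible(x)
}

#' Replicate spatial thinning: one point per cell until all are used
#'
#' Each replicate keeps one uniformly drawn point per occupied thinning
#' cell; replicates accumulate until every original occurrence has been
#' drawn at least once (the coupon-collector stopping rule). A
#' deterministic `"cycle"` mode instead cycles each cell's shuffled points
#' so the replicate count equals the maximum cell multiplicity.
#'
#' @param occ an [occurrence_set].
#' @param grid the covariate [grid_raster] (geometry anchor).
#' @param resolution thinning cell size in map units (>= grid cell size).
#' @param mode `"random"` (stop when all covered) or `"cycle"`.
#' @param max_replicates safety cap for `"random"` mode.
#' @param seed RNG seed.
#' @return List of class `replicate_set`: `replicates` (list of
#'   occurrence tibbles, each with a `replicate` column), `coverage`
#'   (integer per original row: number of replicates containing it),
#'   `n_replicates`.
#' @export
thin_replicates <- function(occ, grid, resolution, mode = c("random", "cycle"),
                            max_replicates = 10000, seed = 1) {
  mode <- match.arg(mode)
  if (resolution < grid$cellsize) {
    stop("resolution must be >= the grid cell size", call. = FALSE)
  }
  set.seed(seed)
  bc <- max(1L, round(resolution / grid$cellsize))
  agg_grid <- grid_raster(
    matrix(0, ceiling(nrow(grid$values) / bc), ceiling(ncol(grid$values) / bc)),
    xmin = grid$xmin, ymax = grid$ymax, cellsize = bc * grid$cellsize)
  cellv <- cell_at(agg_grid, occ$x, occ$y)$cell
  groups <- split(seq_len(nrow(occ)), cellv)
  coverage <- integer(nrow(occ))
  reps <- list()
  if (mode == "cycle") {
    perms <- lapply(groups, function(g) g[sample.int(length(g))])
    n_rep <- max(lengths(groups))
    for (k in seq_len(n_rep)) {
      pick <- vapply(perms, function(g) g[((k - 1L) %% length(g)) + 1L],
                     integer(1))
      coverage[pick] <- coverage[pick] + 1L
      rep_k <- occ[sort(pick), ]
      rep_k$replicate <- k
      reps[[k]] <- rep_k
    }
  } else {
    k <- 0L
    while (any(coverage == 0L) && k < max_replicates) {
      k <- k + 1L
      pick <- vapply(groups, function(g)
        if (length(g) == 1L) g else g[sample.int(length(g), 1L)], integer(1))
      coverage[pick] <- coverage[pick] + 1L
      rep_k <- occ[sort(pick), ]
      rep_k$replicate <- k
      reps[[k]] <- rep_k
    }
  }
  structure(list(replicates = reps, coverage = coverage,
                 n_replicates = length(reps)),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %d replicates, %d points each (min coverage %d)\n",
              x$n_replicates, nrow(x$replicates[[1]]), min(x$coverage)))
  invisible(x)
}
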