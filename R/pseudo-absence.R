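#' Generate pseudo-absence points
#'
#' Two strategies for background/pseudo-absence generation from
#' presence-only data, both drawing `multiplier x n` cells without
#' replacement from the valid (non-nodata) cells not occupied by any
#' parent occurrence, then jittering one point uniformly within each
#' drawn cell:
#'
#' * `generate_random()` — uniform over valid unoccupied cells ("Random
#'   Pts"): ignores sampling effort.
#' * `generate_weighted()` — cell selection probability proportional to a
#'   sampling-effort intensity surface ("Weighted Pts"): reproduces the
#'   occurrences' sampling-bias signature so that presences and
#'   pseudo-absences share it.
#'
#' @param occ parent [occurrence_set] (prepared, before thinning).
#' @param grid the covariate [grid_raster]; `NA` cells are invalid.
#' @param multiplier pseudo-absences per occurrence (default 4).
#' @param jitter logical; place points uniformly within cells (otherwise
#'   at cell centers).
#' @param seed RNG seed.
#' @return A tibble of class `pseudo_absence_set` with columns `x`, `y`;
#'   attributes `strategy` and `multiplier`.
#' @export
generate_random <- function(occ, grid, multiplier = 4, jitter = TRUE,
                            seed = 1) {
  draw_pabs(occ, grid, multiplier, effort = NULL, jitter = jitter,
            seed = seed, strategy = "random")
}

#' @param effort a [grid_raster] of sampling-effort intensity on the same
#'   grid (e.g. from [density_surface()]).
#' @rdname generate_random
#' @export
generate_weighted <- function(occ, effort, grid, multiplier = 4,
                              jitter = TRUE, seed = 1) {
  stop_if_grid_mismatch(grid, effort, "grid and effort")
  draw_pabs(occ, grid, multiplier, effort = effort, jitter = jitter,
            seed = seed, strategy = "weighted")
}

draw_pabs <- function(occ, grid, multiplier, effort, jitter, seed, strategy) {
  if (multiplier <= 0) stop("multiplier must be positive", call. = FALSE)
  set.seed(seed)
  nr <- nrow(grid$values)
  occ_cells <- unique(cell_at(grid, occ$x, occ$y)$cell)
  valid <- which(!is.na(as.vector(grid$values)))
  valid <- setdiff(valid, occ_cells)
  n_draw <- round(multiplier * nrow(occ))
  if (!is.null(effort)) {
    w <- as.vector(effort$values)[valid]
    w[is.na(w)] <- 0
    pos <- w > 0
    if (sum(pos) < n_draw) {
      stop(sprintf(
        "capacity: only %d unoccupied cells with positive effort for %d pseudo-absences",
        sum(pos), n_draw), call. = FALSE)
    }
    cells <- sample(valid[pos], n_draw, prob = w[pos])
  } else {
    if (length(valid) < n_draw) {
      stop(sprintf("capacity: only %d valid unoccupied cells for %d pseudo-absences",
                   length(valid), n_draw), call. = FALSE)
    }
    cells <- sample(valid, n_draw)
  }
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  s <- grid$cellsize
  u <- if (jitter) stats::runif(n_draw) else rep(0.5, n_draw)
  v <- if (jitter) stats::runif(n_draw) else rep(0.5, n_draw)
  out <- tibble::tibble(x = grid$xmin + (col - 1L) * s + u * s,
                        y = grid$ymax - (row - 1L) * s - v * s)
  attr(out, "strategy") <- strategy
  attr(out, "multiplier") <- multiplier
  class(out) <- c("pseudo_absence_set", class(out))
  out
}

#' Assemble a training table from presences and pseudo-absences
#'
#' Binds presence rows (`response = 1`) and pseudo-absence rows
#' (`response = 0`), extracts the covariate stack at every point, and
#' drops rows with missing covariate values. When replicate lists are
#' supplied (from [thin_replicates()]), occurrence replicate `k` is
#' paired with pseudo-absence replicate `k` (the shorter list recycling
#' cyclically) and a `replicate` column is added.
#'
#' @param presences an [occurrence_set], or a `replicate_set` of them.
#' @param absences a `pseudo_absence_set`, or a `replicate_set`.
#' @param stack the covariate [raster_stack] (transforms applied here).
#' @return Tibble with `x`, `y`, covariate columns, `response` (0/1) and
#'   `replicate` (1 when unthinned input was given).
#' @export
build_training_table <- function(presences, absences, stack) {
  stack <- apply_transforms(stack)
  as_list <- function(obj) {
    if (inherits(obj, "replicate_set")) obj$replicates else list(obj)
  }
  pres <- as_list(presences)
  abs_ <- as_list(absences)
  n_rep <- max(length(pres), length(abs_))
  rows <- vector("list", n_rep)
  for (k in seq_len(n_rep)) {
    p <- pres[[((k - 1L) %% length(pres)) + 1L]]
    a <- abs_[[((k - 1L) %% length(abs_)) + 1L]]
    tab <- dplyr::bind_rows(
      tibble::tibble(x = p$x, y = p$y, response = 1),
      tibble::tibble(x = a$x, y = a$y, response = 0))
    tab$replicate <- k
    rows[[k]] <- tab
  }
  out <- extract_covariates(stack, dplyr::bind_rows(rows))
  out <- out[stats::complete.cases(out), ]
  covs <- setdiff(names(out), c("x", "y", "response", "replicate"))
  attr(out, "covariates") <- covs
  attr(out, "specs") <- stack$specs
  out
}
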