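#' Clean and deduplicate occurrence records
#'
#' Applies, in order: (1) temporal window filter on `date` (records with a
#' missing date pass), (2) plausibility mask filter (records on masked-out
#' or out-of-extent cells are dropped), (3) cell-level deduplication at
#' the covariate grid resolution — at most one record per grid cell per
#' source, the first record in each cell winning. Removal counts by reason
#' are attached as the `removals` attribute and reported with `message()`.
#'
#' @param occ an [occurrence_set] tibble.
#' @param grid the covariate [grid_raster] defining resolution and extent.
#' @param window integer `c(first, last)` year window, or `NULL` to skip.
#' @param mask optional [grid_raster]; cells that are `NA` or `0` are
#'   implausible and records there are removed.
#' @return The filtered [occurrence_set]; attribute `removals` is a tibble
#'   of `(reason, n)`.
#' @export
prepare_occurrences <- function(occ, grid, window = c(1970, 2012),
                                mask = NULL) {
  n0 <- nrow(occ)
  out <- tibble::as_tibble(occ)
  rem <- list()

  if (!is.null(window)) {
    drop <- !is.na(out$date) & (out$date < window[1] | out$date > window[2])
    rem$temporal <- sum(drop)
    out <- out[!drop, ]
  } else rem$temporal <- 0L

  idx <- cell_at(grid, out$x, out$y)
  inside <- !is.na(idx$cell)
  if (!is.null(mask)) {
    stop_if_grid_mismatch(grid, mask, "grid and mask")
    mv <- extract_values(mask, out$x, out$y)
    inside <- inside & !is.na(mv) & mv != 0
  }
  rem$implausible <- sum(!inside)
  out <- out[inside, ]
  idx <- idx[inside, ]

  dup <- duplicated(paste(idx$cell, out$source))
  rem$duplicate <- sum(dup)
  out <- out[!dup, ]

  if (nrow(out) == 0) stop("no occurrences left after preparation",
                           call. = FALSE)
  removals <- tibble::tibble(reason = names(rem),
                             n = as.integer(unlist(rem)))
  message(sprintf("prepare_occurrences: %d -> %d (temporal %d, implausible %d, duplicate %d)",
                  n0, nrow(out), rem$temporal, rem$implausible, rem$duplicate))
  attr(out, "removals") <- removals
  class(out) <- c("occurrence_set", setdiff(class(out), "occurrence_set"))
  out
}

#' Merge expert and citizen occurrence sets
#'
#' Union with cell-level deduplication across sources at the covariate
#' grid resolution; when a cell holds records from both sources the expert
#' record is kept (provenance priority).
#'
#' @param expert,citizen prepared [occurrence_set]s on the same grid.
#' @param grid the covariate [grid_raster].
#' @return Combined [occurrence_set].
#' @export
merge_datasets <- function(expert, citizen, grid) {
  all <- dplyr::bind_rows(tibble::as_tibble(expert), tibble::as_tibble(citizen))
  idx <- cell_at(grid, all$x, all$y)
  if (anyNA(idx$cell)) {
    stop("grid mismatch: some points fall outside the covariate grid",
         call. = FALSE)
  }
  # expert first so duplicated() keeps the expert record in shared cells
  ord <- order(all$source != "expert")
  all <- all[ord, ]
  keep <- !duplicated(idx$cell[ord])
  out <- all[keep, ]
  class(out) <- c("occurrence_set", setdiff(class(out), "occurrence_set"))
  out
}

#' Screen covariates for correlation and collinearity
#'
#' Computes the Spearman rank-correlation matrix and variance inflation
#' factors of the (transformed) continuous covariates sampled at the
#' supplied points, then iteratively removes covariates until no pair has
#' `|rho| >= rho_max` and no VIF is `>= vif_max`. Within a violating pair
#' (or the worst VIF offender), the covariate with the lower ecological
#' priority rank is removed. Categorical covariates are exempt and always
#' retained.
#'
#' @param stack a [raster_stack]; declared transforms are applied first.
#' @param points data frame of `x`, `y` sample locations (occurrences plus
#'   background; >= 30 rows).
#' @param rho_max Spearman cutoff (default 0.7).
#' @param vif_max VIF cutoff (default 3).
#' @return A list of class `screening_report`: `spearman` (matrix),
#'   `vif` (named numeric, final round), `removed` (tibble of
#'   `covariate`, `reason`), `retained` (character).
#' @export
screen_covariates <- function(stack, points, rho_max = 0.7, vif_max = 3) {
  if (nrow(points) < 30) stop("need at least 30 sample points", call. = FALSE)
  stack <- apply_transforms(stack)
  specs <- stack$specs
  cont <- specs$name[specs$kind == "continuous"]
  if (length(cont) < 2) stop("need at least 2 continuous covariates",
                             call. = FALSE)
  vals <- extract_covariates(stack, points[, c("x", "y")])
  X <- as.data.frame(vals[, cont, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  prio <- stats::setNames(specs$priority[match(cont, specs$name)], cont)

  spearman_full <- stats::cor(X, method = "spearman")
  removed <- tibble::tibble(covariate = character(), reason = character())
  active <- cont

  vif_of <- function(cols) {
    vapply(cols, function(v) {
      others <- setdiff(cols, v)
      if (!length(others)) return(1)
      fit <- stats::lm(stats::reformulate(others, response = v), data = X)
      # an exact linear combination gives a perfect fit; that is the case
      # the VIF rule exists to catch, so the lm warning is expected
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }

  repeat {
    if (length(active) < 2) break
    rho <- stats::cor(X[, active, drop = FALSE], method = "spearman")
    diag(rho) <- 0
    worst <- which(abs(rho) == max(abs(rho)), arr.ind = TRUE)[1, ]
    if (max(abs(rho)) >= rho_max) {
      pair <- active[worst]
      victim <- pair[which.min(prio[pair])]
      removed <- dplyr::bind_rows(removed, tibble::tibble(
        covariate = victim,
        reason = sprintf("|rho| >= %.2f (with %s, rho = %.3f)", rho_max,
                         setdiff(pair, victim), rho[worst[1], worst[2]])))
      active <- setdiff(active, victim)
      next
    }
    v <- vif_of(active)
    if (max(v) >= vif_max) {
      offenders <- active[v == max(v)]
      victim <- offenders[which.min(prio[offenders])]
      removed <- dplyr::bind_rows(removed, tibble::tibble(
        covariate = victim,
        reason = sprintf("VIF >= %.2f (VIF = %.3g)", vif_max, max(v))))
      active <- setdiff(active, victim)
      next
    }
    break
  }
  if (!length(active)) stop("screening removed every continuous covariate",
                            call. = FALSE)
  retained <- c(active, specs$name[specs$kind == "categorical"])
  structure(list(
    spearman = spearman_full,
    vif = if (length(active) >= 2) vif_of(active) else
      stats::setNames(1, active),
    removed = removed,
    retained = retained
  ), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n retained:", paste(x$retained, collapse = ", "),
      "\n")
  if (nrow(x$removed)) {
    cat(" removed:\n")
    for (i in seq_len(nrow(x$removed))) {
      cat("  -", x$removed$covariate[i], "|", x$removed$reason[i], "\n")
    }
  } else cat(" removed: none\n")
  invisible(x)
}
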