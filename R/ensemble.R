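#' Build a Kappa-weighted ensemble specification
#'
#' Member weights are proportional to each member's cross-validated Kappa
#' score; members with Kappa <= 0 are excluded with a warning and the
#' remaining weights renormalized to sum to 1.
#'
#' @param models list of fitted `sdm_model`s.
#' @param kappas numeric vector of mean CV Kappa scores, same length.
#' @param labels optional member labels.
#' @return Object of class `ensemble_spec`: `members` (models), `weights`
#'   and a `table` tibble of `label`, `kappa`, `weight`.
#' @export
build_ensemble <- function(models, kappas, labels = NULL) {
  stopifnot(length(models) == length(kappas))
  if (is.null(labels)) {
    labels <- vapply(models, function(m) m$algorithm, "")
    labels <- make.unique(labels)
  }
  keep <- kappas > 0
  if (!any(keep)) stop("ensemble degenerate: no member has Kappa > 0",
                       call. = FALSE)
  if (any(!keep)) {
    warning("excluding member(s) with Kappa <= 0: ",
            paste(labels[!keep], collapse = ", "))
  }
  w <- kappas[keep] / sum(kappas[keep])
  structure(list(
    members = models[keep], weights = w,
    table = tibble::tibble(label = labels[keep], kappa = kappas[keep],
                           weight = w)
  ), class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat("<ensemble_spec>", length(x$members), "members\n")
  print(x$table)
  invisible(x)
}

#' Project an ensemble onto a covariate stack
#'
#' Per-cell weighted mean of member probability maps; a cell is nodata
#' whenever any member covariate is nodata there (strict propagation).
#'
#' @param spec an `ensemble_spec`.
#' @param stack the covariate [raster_stack].
#' @return A [grid_raster] of ensemble occurrence probability in
#'   \[0, 1\], on the stack's grid.
#' @export
project_ensemble <- function(spec, stack) {
  g0 <- stack$layers[[1]]
  acc <- matrix(0, nrow(g0$values), ncol(g0$values))
  na_mask <- matrix(FALSE, nrow(g0$values), ncol(g0$values))
  for (i in seq_along(spec$members)) {
    pm <- stats::predict(spec$members[[i]], stack)
    na_mask <- na_mask | is.na(pm$values)
    v <- pm$values
    v[is.na(v)] <- 0
    acc <- acc + spec$weights[i] * v
  }
  acc[na_mask] <- NA_real_
  grid_raster(acc, xmin = g0$xmin, ymax = g0$ymax, cellsize = g0$cellsize,
              crs = g0$crs)
}

#' Classify a probability map into suitability bands
#'
#' @param prob a probability [grid_raster].
#' @param breaks increasing cut points in (0, 1).
#' @return Categorical [grid_raster] with codes `1..length(breaks)+1`.
#' @export
classify_map <- function(prob, breaks = c(0.25, 0.6, 0.75)) {
  cls <- matrix(as.numeric(cut(prob$values, c(-Inf, breaks, Inf))),
                nrow(prob$values))
  grid_raster(cls, xmin = prob$xmin, ymax = prob$ymax,
              cellsize = prob$cellsize, crs = prob$crs, categorical = TRUE)
}
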