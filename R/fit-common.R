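# Shared contract for fitted SDMs: every fitted object is an `sdm_model`
# with an algorithm tag, the covariates used, stored training rows (for
# partial-dependence curves and permutation importance), and a uniform
# predict() returning probabilities in [0, 1].

new_sdm_model <- function(algorithm, subclass, covariates, kinds, fit,
                          training, logLik, null_deviance, k, n,
                          tuning = NULL, extra = list()) {
  structure(list(
    algorithm = algorithm, covariates = covariates, kinds = kinds,
    fit = fit, training = training, logLik = logLik,
    deviance = -2 * logLik, null_deviance = null_deviance,
    k = k, n = n, tuning = tuning, extra = extra
  ), class = c(subclass, "sdm_model"))
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model:%s> %d covariates (%s), n = %d, k = %d\n",
              x$algorithm, length(x$covariates),
              paste(x$covariates, collapse = ", "), x$n, x$k))
  cat(sprintf("  logLik = %.3f, deviance = %.3f (null %.3f, %.1f%% explained)\n",
              x$logLik, x$deviance, x$null_deviance,
              100 * (x$null_deviance - x$deviance) / x$null_deviance))
  if (!is.null(x$tuning$selected)) {
    cat("  tuning:", paste(names(x$tuning$selected),
                           unlist(x$tuning$selected), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

bernoulli_loglik <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

null_deviance_of <- function(y) {
  -2 * bernoulli_loglik(y, mean(y))
}

# Newdata assembly: accepts a tibble with covariate columns or a
# raster_stack; returns list(data = tibble, shape = NULL or grid template).
resolve_newdata <- function(object, newdata) {
  if (inherits(newdata, "raster_stack")) {
    newdata <- apply_transforms(newdata)
    miss <- setdiff(object$covariates, names(newdata$layers))
    if (length(miss)) {
      stop("missing covariate raster(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    g0 <- newdata$layers[[1]]
    cols <- lapply(object$covariates, function(nm) {
      v <- as.vector(newdata$layers[[nm]]$values)
      if (object$kinds[[nm]] == "categorical") factor(v) else v
    })
    names(cols) <- object$covariates
    list(data = tibble::as_tibble(cols), template = g0)
  } else {
    newdata <- tibble::as_tibble(newdata)
    miss <- setdiff(object$covariates, names(newdata))
    if (length(miss)) {
      stop("missing covariate column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    list(data = newdata, template = NULL)
  }
}

#' Predict occurrence probability from a fitted SDM
#'
#' @param object an `sdm_model`.
#' @param newdata a tibble with the model's covariate columns, or a
#'   [raster_stack] (prediction is then returned as a [grid_raster] with
#'   `NA` wherever any covariate is `NA`).
#' @param ... unused.
#' @return Numeric vector of probabilities in \[0, 1\], or a
#'   [grid_raster] for stack input.
#' @export
predict.sdm_model <- function(object, newdata, ...) {
  res <- resolve_newdata(object, newdata)
  na_mask <- !stats::complete.cases(res$data[, object$covariates,
                                             drop = FALSE])
  data <- res$data
  if (any(na_mask)) {
    # fill NAs with a valid placeholder so every engine can run, then
    # restore strict nodata propagation
    for (nm in object$covariates) {
      v <- data[[nm]]
      if (anyNA(v)) {
        filler <- if (is.factor(v)) levels(v)[1] else
          mean(object$training[[nm]])
        v[is.na(v)] <- filler
        data[[nm]] <- v
      }
    }
  }
  p <- sdm_predict_prob(object, data)
  p[na_mask] <- NA_real_
  if (is.null(res$template)) return(p)
  tpl <- res$template
  out <- grid_raster(matrix(p, nrow(tpl$values), ncol(tpl$values)),
                     xmin = tpl$xmin, ymax = tpl$ymax,
                     cellsize = tpl$cellsize, crs = tpl$crs)
  out
}

sdm_predict_prob <- function(object, data) {
  UseMethod("sdm_predict_prob")
}

#' Partial-dependence response curve of one covariate
#'
#' Varies the target covariate over its training range at evenly spaced
#' points (or its levels, for a categorical covariate), holding the other
#' covariates at their training values and averaging the predictions.
#'
#' @param model an `sdm_model`.
#' @param covariate covariate name (must have been in the model).
#' @param n_points number of evaluation points for continuous covariates.
#' @param max_rows training rows subsampled for the average (speed).
#' @return Tibble with `covariate`, `value`, `prediction`.
#' @export
response_curve <- function(model, covariate, n_points = 100,
                           max_rows = 200) {
  if (!covariate %in% model$covariates) {
    stop("covariate not in the model: ", covariate, call. = FALSE)
  }
  tr <- model$training
  if (nrow(tr) > max_rows) {
    tr <- tr[unique(round(seq(1, nrow(tr), length.out = max_rows))), ]
  }
  if (model$kinds[[covariate]] == "categorical") {
    grid_vals <- levels(tr[[covariate]])
  } else {
    rng <- range(model$training[[covariate]])
    grid_vals <- seq(rng[1], rng[2], length.out = n_points)
  }
  preds <- vapply(grid_vals, function(v) {
    tr2 <- tr
    tr2[[covariate]] <- if (is.character(v))
      factor(v, levels = levels(tr[[covariate]])) else v
    mean(sdm_predict_prob(model, tr2))
  }, numeric(1))
  tibble::tibble(covariate = covariate,
                 value = if (is.character(grid_vals[1]))
                   as.numeric(grid_vals) else as.numeric(grid_vals),
                 prediction = preds)
}

#' Broom-style one-row model summary
#'
#' @param x an `sdm_model`.
#' @param ... unused.
#' @return One-row tibble with `algorithm`, `n`, `k`, `logLik`,
#'   `deviance`, `null_deviance`, `deviance_explained` (percent), `AICc`.
#' @export
glance.sdm_model <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm, n = x$n, k = x$k, logLik = x$logLik,
    deviance = x$deviance, null_deviance = x$null_deviance,
    deviance_explained = 100 * (x$null_deviance - x$deviance) /
      x$null_deviance,
    AICc = aicc(x$logLik, x$k, x$n)
  )
}

#' Tidy per-term parameters of a fitted SDM
#'
#' GLM: coefficient table; MaxEnt: nonzero feature weights; BRT:
#' per-covariate split gain summary.
#'
#' @param x an `sdm_model`.
#' @param ... unused.
#' @return Tibble with `term` and `estimate` columns (plus standard
#'   errors and tests where the engine provides them).
#' @export
tidy.sdm_model <- function(x, ...) {
  tibble::tibble(term = "(no per-term view for this algorithm)",
                 estimate = NA_real_)
}

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Serialize a fitted SDM to a JSON container
#'
#' Writes a documented JSON object: algorithm tag, covariates and kinds,
#' standardization constants, tuning record, fit statistics, and the
#' engine parameters (GLM coefficients; MaxEnt nonzero weights and basis
#' definition; BRT boosted-tree dump, base64-encoded).
#'
#' @param model an `sdm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    algorithm = model$algorithm,
    covariates = model$covariates,
    kinds = as.list(model$kinds),
    n = model$n, k = model$k, logLik = model$logLik,
    deviance = model$deviance, null_deviance = model$null_deviance,
    tuning = model$tuning,
    parameters = sdm_serialize(model)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

sdm_serialize <- function(model) UseMethod("sdm_serialize")

#' @export
sdm_serialize.default <- function(model) list()
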