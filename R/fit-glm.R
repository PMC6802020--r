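#' Fit a quadratic logistic regression SDM
#'
#' Logistic regression (binomial family, logit link) with linear plus
#' quadratic terms for every continuous covariate and dummy coding for
#' categorical covariates, no interactions. Continuous covariates are
#' z-scored before the quadratic expansion for IRLS stability; the
#' standardization constants are stored in the model so predictions are
#' unchanged.
#'
#' @param table a training tibble from [build_training_table()] (columns:
#'   covariates, `response` in 0/1).
#' @param covariates character vector of covariate names to use; defaults
#'   to every covariate in the table.
#' @param quadratic include squared terms for continuous covariates.
#' @return An `sdm_model` of subclass `sdm_glm`.
#' @export
fit_glm <- function(table, covariates = NULL, quadratic = TRUE) {
  prep <- prep_table(table, covariates)
  covariates <- prep$covariates
  k_expected <- 1 + sum(prep$kinds == "continuous") * (1 + quadratic) +
    sum(vapply(prep$data[covariates[prep$kinds == "categorical"]],
               function(f) nlevels(f) - 1L, integer(1)))
  if (nrow(prep$data) < 10 * k_expected) {
    warning(sprintf("n = %d is below 10 x %d parameters; estimates may be unstable",
                    nrow(prep$data), k_expected))
  }
  z <- standardize(prep$data, covariates, prep$kinds)
  terms <- character()
  for (nm in covariates) {
    if (prep$kinds[[nm]] == "continuous") {
      terms <- c(terms, nm, if (quadratic) sprintf("I(%s^2)", nm))
    } else {
      terms <- c(terms, nm)
    }
  }
  fml <- stats::reformulate(terms, response = "response")
  fit <- stats::glm(fml, family = stats::binomial(),
                    data = cbind(z$data, response = prep$data$response),
                    control = stats::glm.control(maxit = 100, epsilon = 1e-10))
  if (!fit$converged) {
    stop("GLM did not converge within 100 IRLS iterations", call. = FALSE)
  }
  p <- stats::fitted(fit)
  if (any(p < 1e-10 | p > 1 - 1e-10)) {
    warning("fitted probabilities of 0 or 1 occurred: possible complete separation")
  }
  y <- prep$data$response
  ll <- bernoulli_loglik(y, p)
  m <- new_sdm_model(
    algorithm = "GLM", subclass = "sdm_glm",
    covariates = covariates, kinds = prep$kinds, fit = fit,
    training = prep$data, logLik = ll,
    null_deviance = null_deviance_of(y),
    k = length(stats::coef(fit)), n = nrow(prep$data),
    tuning = list(selected = list(quadratic = quadratic)),
    extra = list(scaling = z$scaling, quadratic = quadratic)
  )
  m
}

# Validate/derive covariate set and kinds from the table attributes.
prep_table <- function(table, covariates) {
  table <- tibble::as_tibble(table)
  all_cov <- attr(table, "covariates") %||%
    setdiff(names(table), c("x", "y", "response", "replicate"))
  if (is.null(covariates)) covariates <- all_cov
  miss <- setdiff(covariates, names(table))
  if (length(miss)) stop("covariates missing from table: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"response" %in% names(table)) stop("table has no `response` column",
                                          call. = FALSE)
  if (length(unique(table$response)) < 2) {
    stop("both response classes must be present", call. = FALSE)
  }
  kinds <- vapply(covariates, function(nm)
    if (is.factor(table[[nm]]) || is.character(table[[nm]]))
      "categorical" else "continuous", "")
  data <- table[, c(covariates, "response")]
  for (nm in covariates[kinds == "categorical"]) {
    data[[nm]] <- factor(data[[nm]])
  }
  data <- data[stats::complete.cases(data), ]
  list(data = data, covariates = covariates, kinds = kinds)
}

standardize <- function(data, covariates, kinds, scaling = NULL) {
  cont <- covariates[kinds == "continuous"]
  if (is.null(scaling)) {
    scaling <- list(
      center = vapply(data[cont], mean, numeric(1)),
      scale = vapply(data[cont], function(v) {
        s <- stats::sd(v); if (s == 0) 1 else s
      }, numeric(1)))
  }
  for (nm in cont) {
    data[[nm]] <- (data[[nm]] - scaling$center[[nm]]) / scaling$scale[[nm]]
  }
  list(data = data, scaling = scaling)
}

#' @export
sdm_predict_prob.sdm_glm <- function(object, data) {
  covs <- object$covariates
  d <- data[, covs, drop = FALSE]
  for (nm in covs[object$kinds == "categorical"]) {
    d[[nm]] <- factor(d[[nm]], levels = levels(object$training[[nm]]))
  }
  d <- standardize(d, covs, object$kinds, object$extra$scaling)$data
  as.numeric(stats::predict(object$fit, newdata = d, type = "response"))
}

#' @export
tidy.sdm_glm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @export
sdm_serialize.sdm_glm <- function(model) {
  list(coefficients = as.list(stats::coef(model$fit)),
       scaling = lapply(model$extra$scaling, as.list),
       quadratic = model$extra$quadratic)
}
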