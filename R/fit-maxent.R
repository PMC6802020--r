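#' Tune and fit a maximum-entropy-style SDM
#'
#' Presence–background maximum entropy estimation via its penalized
#' logistic regression equivalence: an L1-regularized logistic regression
#' of presences (1) against background/pseudo-absence rows (0) on the
#' expanded MaxEnt feature basis — linear, quadratic, product, hinge,
#' threshold, and categorical features, each scaled to \[0, 1\] over the
#' training rows. Hinge and threshold features take knots at the training
#' deciles (10 per covariate). The overall regularization multiplier is
#' selected from a grid (default 0.2–5 by 0.2) by k-fold cross-validated
#' predictive log-likelihood.
#'
#' @param table training tibble (presences + background rows).
#' @param covariates covariate names (default: all in the table).
#' @param features feature classes to build; any subset of
#'   `c("linear", "quadratic", "product", "hinge", "threshold",
#'   "categorical")`.
#' @param reg_grid regularization multipliers scanned.
#' @param folds CV folds (default 5).
#' @param n_knots hinge/threshold knots per covariate.
#' @param seed RNG seed for fold assignment.
#' @return An `sdm_model` of subclass `sdm_maxent`; `k` is the number of
#'   nonzero feature weights plus intercept.
#' @export
tune_fit_maxent <- function(table, covariates = NULL,
                            features = c("linear", "quadratic", "product",
                                         "hinge", "threshold", "categorical"),
                            reg_grid = seq(0.2, 5, by = 0.2), folds = 5,
                            n_knots = 10, seed = 1) {
  features <- match.arg(features, several.ok = TRUE)
  prep <- prep_table(table, covariates)
  covariates <- prep$covariates
  basis <- maxent_basis(prep$data, covariates, prep$kinds, features, n_knots)
  if (!ncol(basis$matrix)) stop("empty feature basis", call. = FALSE)
  y <- prep$data$response
  X <- basis$matrix

  # map multipliers onto the glmnet lambda scale: lambda_max is the entry
  # point of the path; multiplier 1 sits two decades below it
  n <- length(y)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  lambda_ref <- lambda_max / 100
  lambdas <- sort(unique(reg_grid * lambda_ref), decreasing = TRUE)

  set.seed(seed)
  fold_id <- stratified_folds(y, folds)
  cv_ll <- matrix(0, folds, length(lambdas))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit_f <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = 1,
                            lambda = lambdas, standardize = FALSE)
    p <- stats::predict(fit_f, X[!tr, , drop = FALSE], type = "response")
    # glmnet may stop early on the path; recycle the last fitted column
    p <- p[, pmin(seq_along(lambdas), ncol(p)), drop = FALSE]
    cv_ll[f, ] <- vapply(seq_along(lambdas), function(j)
      bernoulli_loglik(y[!tr], p[, j]), numeric(1))
  }
  mean_ll <- colMeans(cv_ll)
  best_j <- which.max(mean_ll)
  lambda_sel <- lambdas[best_j]
  mult_sel <- lambda_sel / lambda_ref

  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = lambdas, standardize = FALSE)
  beta <- as.numeric(stats::coef(fit, s = lambda_sel, exact = FALSE))
  names(beta) <- c("(Intercept)", colnames(X))
  p_train <- stats::plogis(beta[1] + as.numeric(X %*% beta[-1]))
  ll <- bernoulli_loglik(y, p_train)
  new_sdm_model(
    algorithm = "MAXENT", subclass = "sdm_maxent",
    covariates = covariates, kinds = prep$kinds, fit = beta,
    training = prep$data, logLik = ll,
    null_deviance = null_deviance_of(y),
    k = sum(beta[-1] != 0) + 1L, n = n,
    tuning = list(
      grid = list(multipliers = reg_grid, features = features,
                  n_knots = n_knots),
      cv_table = tibble::tibble(multiplier = lambdas / lambda_ref,
                                lambda = lambdas, cv_logLik = mean_ll),
      selected = list(multiplier = mult_sel, lambda = lambda_sel)),
    extra = list(basis = basis$template)
  )
}

# MaxEnt feature basis. template captures everything needed to rebuild
# identical columns at prediction time (z-scoring constants, knots,
# min/max used for [0,1] scaling, level sets).
maxent_basis <- function(data, covariates, kinds, features, n_knots,
                         template = NULL) {
  build <- is.null(template)
  if (build) {
    template <- list(features = features, n_knots = n_knots, cols = list())
    cont <- covariates[kinds == "continuous"]
    template$center <- vapply(data[cont], mean, numeric(1))
    template$scale <- vapply(data[cont], function(v) {
      s <- stats::sd(v); if (s == 0) 1 else s
    }, numeric(1))
    template$knots <- lapply(data[cont], function(v)
      unique(stats::quantile(v, probs = seq(0.05, 0.95,
                                            length.out = n_knots))))
    template$levels <- lapply(
      data[covariates[kinds == "categorical"]],
      function(f) levels(factor(f)))
    template$range <- lapply(data[cont], range)
  }
  cont <- names(template$center)
  z <- list()
  for (nm in cont) {
    z[[nm]] <- (as.numeric(data[[nm]]) - template$center[[nm]]) /
      template$scale[[nm]]
  }
  cols <- list()
  f <- template$features
  if ("linear" %in% f) for (nm in cont) cols[[paste0("lin:", nm)]] <- z[[nm]]
  if ("quadratic" %in% f) for (nm in cont)
    cols[[paste0("quad:", nm)]] <- z[[nm]]^2
  if ("product" %in% f && length(cont) >= 2) {
    pairs <- utils::combn(cont, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      cols[[paste0("prod:", a, "*", b)]] <- z[[a]] * z[[b]]
    }
  }
  for (nm in cont) {
    x <- as.numeric(data[[nm]])
    rng <- template$range[[nm]]
    for (kn in template$knots[[nm]]) {
      key <- format(kn, digits = 6)
      if ("hinge" %in% f) {
        if (rng[2] > kn) {
          cols[[paste0("hingeF:", nm, "@", key)]] <-
            pmax(0, (x - kn) / (rng[2] - kn))
        }
        if (kn > rng[1]) {
          cols[[paste0("hingeR:", nm, "@", key)]] <-
            pmax(0, (kn - x) / (kn - rng[1]))
        }
      }
      if ("threshold" %in% f) {
        cols[[paste0("thr:", nm, "@", key)]] <- as.numeric(x > kn)
      }
    }
  }
  if ("categorical" %in% f) {
    for (nm in names(template$levels)) {
      fc <- factor(data[[nm]], levels = template$levels[[nm]])
      for (lv in template$levels[[nm]]) {
        cols[[paste0("cat:", nm, "=", lv)]] <- as.numeric(fc == lv)
      }
    }
  }
  M <- do.call(cbind, cols)
  if (build) {
    template$scale01 <- lapply(seq_len(ncol(M)), function(j) {
      r <- range(M[, j]); if (r[2] == r[1]) r[2] <- r[1] + 1; r
    })
    names(template$scale01) <- colnames(M)
  }
  for (j in seq_len(ncol(M))) {
    r <- template$scale01[[colnames(M)[j]]]
    M[, j] <- (M[, j] - r[1]) / (r[2] - r[1])
  }
  list(matrix = M, template = template)
}

#' @export
sdm_predict_prob.sdm_maxent <- function(object, data) {
  d <- data[, object$covariates, drop = FALSE]
  basis <- maxent_basis(d, object$covariates, object$kinds,
                        features = NULL, n_knots = NULL,
                        template = object$extra$basis)
  beta <- object$fit
  miss_rows <- !stats::complete.cases(basis$matrix)
  M <- basis$matrix
  M[miss_rows, ] <- 0
  p <- stats::plogis(beta[1] + as.numeric(M %*% beta[-1]))
  p[miss_rows] <- NA_real_
  p
}

#' @export
tidy.sdm_maxent <- function(x, ...) {
  beta <- x$fit
  nz <- beta[beta != 0]
  tibble::tibble(term = names(nz), estimate = as.numeric(nz))
}

#' @export
sdm_serialize.sdm_maxent <- function(model) {
  beta <- model$fit
  list(weights = as.list(beta[beta != 0]),
       basis = list(
         features = model$extra$basis$features,
         center = as.list(model$extra$basis$center),
         scale = as.list(model$extra$basis$scale),
         knots = lapply(model$extra$basis$knots, as.numeric),
         levels = model$extra$basis$levels))
}
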