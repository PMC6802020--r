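#' Covariate importance, model-specific estimators
#'
#' Three estimators matching each algorithm's convention:
#'
#' * `importance_glm()` — permutation contrast: for each covariate,
#'   permute its column, recompute predictions, and take the absolute
#'   paired t statistic of the per-row change in fit (Bernoulli
#'   log-likelihood contribution before minus after permuting), averaged
#'   over `R` permutations. Raw prediction differences are mean-zero by
#'   symmetry, so the fit contribution is the paired quantity.
#' * `importance_brt()` — split-based: per covariate, the sum of squared
#'   loss improvements (gain) over all splits on it, averaged over trees.
#' * `importance_maxent()` — AUC drop: baseline training AUC minus the
#'   AUC after replacing the covariate with values drawn uniformly across
#'   its training range, averaged over `R` draws and floored at 0.
#'
#' @param model a fitted `sdm_model` of the matching subclass.
#' @param table the training tibble (needed by the GLM and MaxEnt
#'   estimators; must contain `response` for MaxEnt).
#' @param R number of permutation/resampling repeats.
#' @param seed RNG seed.
#' @return Named numeric vector of raw importances (one per covariate).
#' @export
importance_glm <- function(model, table = model$training, R = 10, seed = 1) {
  set.seed(seed)
  tab <- tibble::as_tibble(table)
  y <- tab$response
  ll_rows <- function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    y * log(p) + (1 - y) * log(1 - p)
  }
  base <- ll_rows(sdm_predict_prob(model, tab))
  out <- stats::setNames(numeric(length(model$covariates)),
                         model$covariates)
  for (nm in model$covariates) {
    ts <- numeric(R)
    for (r in seq_len(R)) {
      perm <- tab
      perm[[nm]] <- perm[[nm]][sample.int(nrow(perm))]
      d <- base - ll_rows(sdm_predict_prob(model, perm))
      s <- stats::sd(d)
      ts[r] <- if (s == 0) 0 else
        abs(mean(d) / (s / sqrt(length(d))))
    }
    out[nm] <- mean(ts)
  }
  out
}

#' @rdname importance_glm
#' @export
importance_brt <- function(model) {
  brt_split_gain(model)
}

#' @rdname importance_glm
#' @export
importance_maxent <- function(model, table = model$training, R = 10,
                              seed = 1) {
  set.seed(seed)
  tab <- tibble::as_tibble(table)
  if (length(unique(tab$response)) < 2) {
    stop("importance undefined: both classes must be present", call. = FALSE)
  }
  base_auc <- auc(sdm_predict_prob(model, tab), tab$response)
  out <- stats::setNames(numeric(length(model$covariates)),
                         model$covariates)
  for (nm in model$covariates) {
    drops <- numeric(R)
    for (r in seq_len(R)) {
      mod <- tab
      if (model$kinds[[nm]] == "categorical") {
        lv <- levels(factor(tab[[nm]]))
        mod[[nm]] <- factor(sample(lv, nrow(tab), replace = TRUE),
                            levels = lv)
      } else {
        rng <- range(tab[[nm]])
        mod[[nm]] <- stats::runif(nrow(tab), rng[1], rng[2])
      }
      drops[r] <- base_auc - auc(sdm_predict_prob(model, mod),
                                 tab$response)
    }
    out[nm] <- max(0, mean(drops))
  }
  out
}

#' Standardize raw importances to a 0–100 scale
#'
#' Proportional rescaling so the importances of one model sum to 100;
#' preserves ranking. An all-zero vector stays all zero.
#'
#' @param raw named numeric vector of raw importances (nonnegative).
#' @return Named numeric vector summing to 100 (or all zeros).
#' @export
standardize_importance <- function(raw) {
  raw <- pmax(raw, 0)
  s <- sum(raw)
  if (s == 0) return(raw)
  100 * raw / s
}

#' Importance of a fitted model, dispatched by algorithm
#'
#' @param model an `sdm_model`.
#' @param ... passed to the algorithm-specific estimator.
#' @return Tibble with `covariate`, `raw`, `standardized`.
#' @export
covariate_importance <- function(model, ...) {
  raw <- switch(model$algorithm,
                GLM = importance_glm(model, ...),
                BRT = importance_brt(model),
                MAXENT = importance_maxent(model, ...),
                stop("unknown algorithm", call. = FALSE))
  tibble::tibble(covariate = names(raw), raw = as.numeric(raw),
                 standardized = as.numeric(standardize_importance(raw)))
}

#' Expert-rubric weighted response-curve score
#'
#' Each response curve receives an integer rubric score 0–3 (poor to
#' excellent representation of ecological reality); the model's score is
#' the mean over its K covariates of rubric x standardized importance:
#' `(1/K) sum_k rubric_k * importance_k`.
#'
#' @param rubric named integer vector (values in 0..3), or a list/YAML
#'   mapping covariate -> score.
#' @param importance named numeric vector of standardized importances
#'   (0–100 scale) covering the same covariates.
#' @return The weighted score (scalar).
#' @export
expert_weighted_score <- function(rubric, importance) {
  rubric <- unlist(rubric)
  if (!setequal(names(rubric), names(importance))) {
    stop("rubric and importance must cover the same covariates",
         call. = FALSE)
  }
  if (any(!rubric %in% 0:3)) {
    stop("rubric scores must be integers in 0..3", call. = FALSE)
  }
  mean(rubric[names(importance)] * importance)
}

#' Read an expert rubric from YAML
#' @param path YAML file mapping covariate names to scores 0-3.
#' @return Named integer vector.
#' @export
read_rubric <- function(path) {
  r <- yaml::read_yaml(path)
  stats::setNames(as.integer(unlist(r)), names(r))
}
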