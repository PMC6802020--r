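#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param logL log-likelihood at the optimum.
#' @param k number of estimated parameters.
#' @param n number of observations (must exceed `k + 1`).
#' @return AICc value.
#' @export
aicc <- function(logL, k, n) {
  if (any(n <= k + 1)) {
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  }
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one candidate covariate subset on every replicate
#'
#' @param table training tibble with a `replicate` column.
#' @param covariates the candidate's covariate subset.
#' @param algorithm `"glm"`, `"brt"`, or `"maxent"`.
#' @param ... passed to the fitting function.
#' @return Tibble of class `candidate_fit`: one row per replicate with
#'   `logLik`, `k`, `n`, `AICc`, `deviance`, `null_deviance`; attributes
#'   `covariates` and the last replicate's fitted model.
#' @export
fit_candidate <- function(table, covariates, algorithm = "glm", ...) {
  reps <- sort(unique(table[["replicate"]] %||% 1))
  if (is.null(table[["replicate"]])) table$replicate <- 1
  rows <- list()
  last_fit <- NULL
  for (r in reps) {
    sub <- table[table$replicate == r, ]
    m <- switch(algorithm,
                glm = fit_glm(sub, covariates, ...),
                brt = tune_fit_brt(sub, covariates, ...),
                maxent = tune_fit_maxent(sub, covariates, ...),
                stop("unknown algorithm: ", algorithm, call. = FALSE))
    rows[[length(rows) + 1]] <- tibble::tibble(
      replicate = r, logLik = m$logLik, k = m$k, n = m$n,
      AICc = aicc(m$logLik, m$k, m$n), deviance = m$deviance,
      null_deviance = m$null_deviance)
    last_fit <- m
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "covariates") <- covariates
  attr(out, "model") <- last_fit
  class(out) <- c("candidate_fit", class(out))
  out
}

#' Rank candidate models by mean AICc with Akaike weights
#'
#' Per-replicate metrics are averaged across replicates first, then
#' `wAICc_i = exp(-d_i/2) / sum_j exp(-d_j/2)` with
#' `d_i = AICc_i - min AICc`, and percent deviance explained
#' `100 (D_null - D_model) / D_null`.
#'
#' @param candidates named list of `candidate_fit` tibbles fitted on
#'   identical rows (same replicates and row counts).
#' @return Tibble sorted by `AICc`: `model`, `covariates`, `AICc`,
#'   `dAICc`, `wAICc`, `deviance_explained`, `k`, `n`.
#' @export
rank_candidates <- function(candidates) {
  if (length(candidates) < 1) stop("no candidates", call. = FALSE)
  ns <- lapply(candidates, function(cf) cf$n)
  if (length(unique(vapply(ns, paste, "", collapse = ","))) != 1) {
    stop("candidates were not fitted on identical rows", call. = FALSE)
  }
  tab <- purrr::imap_dfr(candidates, function(cf, nm) {
    tibble::tibble(
      model = nm,
      covariates = paste(attr(cf, "covariates"), collapse = "+"),
      AICc = mean(cf$AICc),
      deviance_explained = mean(100 * (cf$null_deviance - cf$deviance) /
                                  cf$null_deviance),
      k = mean(cf$k), n = mean(cf$n))
  })
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$wAICc <- exp(-tab$dAICc / 2) / sum(exp(-tab$dAICc / 2))
  dplyr::arrange(tab[, c("model", "covariates", "AICc", "dAICc", "wAICc",
                         "deviance_explained", "k", "n")], .data$AICc)
}

#' Two-phase AICc covariate-subset selection
#'
#' Phase 1 ranks a candidate set of climatic covariate subsets and a
#' separate set of nonclimatic subsets independently; the covariates of
#' each group's top-weighted model are pooled. Phase 2 enumerates every
#' non-empty subset of the pooled covariates, ranks them by AICc, and
#' returns the winner. The global model (all pooled covariates) is by
#' construction a member of the phase-2 set.
#'
#' @param table training tibble (with `replicate` column or not).
#' @param climatic_sets,nonclimatic_sets named lists of covariate-name
#'   vectors — the candidate subsets per group.
#' @param algorithm fitting algorithm (phase enumeration is usually run
#'   with `"glm"` for tractability).
#' @param max_pooled enumeration cap on the pooled covariate count.
#' @param ... passed to the fitter.
#' @return List of class `two_phase_selection`: `phase1` (list of two
#'   ranking tibbles), `pooled` (character), `phase2` (ranking tibble),
#'   `best` (covariates of the winner), `best_model` (fitted on the last
#'   replicate).
#' @export
two_phase_select <- function(table, climatic_sets, nonclimatic_sets,
                             algorithm = "glm", max_pooled = 12, ...) {
  if (!length(climatic_sets) || !length(nonclimatic_sets)) {
    stop("both candidate groups must be non-empty", call. = FALSE)
  }
  rank_group <- function(sets) {
    fits <- lapply(sets, function(cv)
      fit_candidate(table, cv, algorithm = algorithm, ...))
    rank_candidates(fits)
  }
  p1_clim <- rank_group(climatic_sets)
  p1_non <- rank_group(nonclimatic_sets)
  pooled <- union(climatic_sets[[p1_clim$model[1]]],
                  nonclimatic_sets[[p1_non$model[1]]])
  if (length(pooled) > max_pooled) {
    stop(sprintf(
      "pooled covariate count %d exceeds the enumeration cap %d; prune the candidate sets",
      length(pooled), max_pooled), call. = FALSE)
  }
  subsets <- unlist(lapply(seq_along(pooled), function(m)
    utils::combn(pooled, m, simplify = FALSE)), recursive = FALSE)
  names(subsets) <- vapply(subsets, paste, "", collapse = "+")
  fits2 <- lapply(subsets, function(cv)
    fit_candidate(table, cv, algorithm = algorithm, ...))
  p2 <- rank_candidates(fits2)
  best_name <- p2$model[1]
  structure(list(
    phase1 = list(climatic = p1_clim, nonclimatic = p1_non),
    pooled = pooled,
    phase2 = p2,
    best = subsets[[best_name]],
    best_model = attr(fits2[[best_name]], "model")
  ), class = "two_phase_selection")
}

#' @export
print.two_phase_selection <- function(x, ...) {
  cat("<two_phase_selection>\n pooled:", paste(x$pooled, collapse = ", "),
      "\n best:", paste(x$best, collapse = ", "),
      sprintf(" (wAICc = %.3f)\n", x$phase2$wAICc[1]))
  invisible(x)
}
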