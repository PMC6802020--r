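#' Area under the ROC curve
#'
#' Rank (Mann–Whitney) formulation: the probability that a randomly
#' chosen presence outscores a randomly chosen absence, ties counted 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's Kappa at the max(sensitivity + specificity) threshold
#'
#' Scans every distinct score value as a classification threshold
#' (predict presence when `score >= threshold`), picks the threshold
#' maximizing sensitivity + specificity (ties broken toward the lower
#' threshold), and returns Cohen's Kappa of the confusion matrix at that
#' threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), both classes present.
#' @return List with `kappa`, `threshold`, `sensitivity`, `specificity`.
#' @export
kappa_max_ss <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("Kappa undefined: both classes must be present", call. = FALSE)
  }
  thr <- sort(unique(scores))
  best <- -Inf; best_t <- thr[1]
  for (t in thr) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / n1
    spec <- sum(!pred & labels == 0) / n0
    if (sens + spec > best + 1e-12) {
      best <- sens + spec
      best_t <- t
    }
  }
  pred <- scores >= best_t
  cohen_kappa_at(pred, labels, best_t)
}

cohen_kappa_at <- function(pred, labels, threshold) {
  n <- length(labels)
  tp <- sum(pred & labels == 1); tn <- sum(!pred & labels == 0)
  fp <- sum(pred & labels == 0); fn <- sum(!pred & labels == 1)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  list(kappa = kappa, threshold = threshold,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Stratified k-fold cross-validation of an SDM specification
#'
#' Random stratified folds (each fold holds out 1/k of each class, i.e.
#' an 80/20 train/test split for the default 5 folds); the model is refit
#' on each training portion and scored on the held-out portion with AUC
#' and Kappa at the max(sensitivity+specificity) threshold. With a
#' `replicate` column, the protocol runs per replicate.
#'
#' @param table training tibble.
#' @param fitter function `(table) -> sdm_model`, e.g.
#'   `function(t) fit_glm(t, covs)`.
#' @param folds number of folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param algorithm,dataset,strategy labels copied into the records.
#' @return Tibble of evaluation records: one row per replicate x fold
#'   with `protocol`, `dataset`, `strategy`, `algorithm`, `replicate`,
#'   `fold`, `auc`, `kappa`, `threshold`, `n_test`.
#' @export
cross_validate <- function(table, fitter, folds = 5, seed = 1,
                           algorithm = "model", dataset = "data",
                           strategy = "random") {
  table <- tibble::as_tibble(table)
  if (is.null(table[["replicate"]])) table$replicate <- 1
  set.seed(seed)
  rows <- list()
  for (r in sort(unique(table$replicate))) {
    sub <- table[table$replicate == r, ]
    if (sum(sub$response == 1) < folds || sum(sub$response == 0) < folds) {
      stop("need at least `folds` rows of each class per replicate",
           call. = FALSE)
    }
    fold_id <- stratified_folds(sub$response, folds)
    for (f in seq_len(folds)) {
      train <- sub[fold_id != f, ]
      test <- sub[fold_id == f, ]
      m <- fitter(train)
      p <- stats::predict(m, test)
      ok <- !is.na(p)
      a <- auc(p[ok], test$response[ok])
      kp <- kappa_max_ss(p[ok], test$response[ok])
      rows[[length(rows) + 1]] <- tibble::tibble(
        protocol = "cv", dataset = dataset, strategy = strategy,
        algorithm = algorithm, replicate = r, fold = f,
        region = NA_integer_, auc = a, kappa = kp$kappa,
        threshold = kp$threshold, n_test = sum(ok))
    }
  }
  dplyr::bind_rows(rows)
}

#' Leave-one-region-out transferability validation
#'
#' For every region holding at least `min_count` occurrence (presence)
#' points, the model is calibrated on all other regions' rows and scored
#' on the held-out region's presences and pseudo-absences. Regions below
#' the count threshold are reported as not evaluated.
#'
#' @param table training tibble with `x`, `y` columns.
#' @param regions a categorical [grid_raster] partitioning the extent.
#' @param fitter function `(table) -> sdm_model`.
#' @param min_count minimum presence count for a region to be evaluated
#'   (default 25).
#' @param algorithm,dataset,strategy labels copied into the records.
#' @return List with `records` (evaluation tibble, one row per evaluated
#'   region x replicate) and `regions` (tibble of `region`, `n_presence`,
#'   `evaluated`).
#' @export
out_of_region <- function(table, regions, fitter, min_count = 25,
                          algorithm = "model", dataset = "data",
                          strategy = "random") {
  table <- tibble::as_tibble(table)
  if (is.null(table[["replicate"]])) table$replicate <- 1
  table$region <- extract_values(regions, table$x, table$y)
  if (anyNA(table$region)) {
    stop("region partition does not cover every row", call. = FALSE)
  }
  pres_counts <- table(table$region[table$response == 1 &
                                      table$replicate ==
                                      min(table$replicate)])
  status <- tibble::tibble(
    region = as.integer(names(pres_counts)),
    n_presence = as.integer(pres_counts))
  status$evaluated <- status$n_presence >= min_count
  eligible <- status$region[status$evaluated]
  if (length(eligible) < 2) {
    stop("fewer than 2 regions meet the occurrence-count threshold",
         call. = FALSE)
  }
  rows <- list()
  for (r in sort(unique(table$replicate))) {
    sub <- table[table$replicate == r, ]
    for (reg in eligible) {
      train <- sub[sub$region != reg, ]
      test <- sub[sub$region == reg, ]
      if (length(unique(test$response)) < 2 ||
          length(unique(train$response)) < 2) next
      m <- fitter(train)
      p <- stats::predict(m, test)
      ok <- !is.na(p)
      a <- auc(p[ok], test$response[ok])
      kp <- kappa_max_ss(p[ok], test$response[ok])
      rows[[length(rows) + 1]] <- tibble::tibble(
        protocol = "out_of_region", dataset = dataset, strategy = strategy,
        algorithm = algorithm, replicate = r, fold = NA_integer_,
        region = as.integer(reg), auc = a, kappa = kp$kappa,
        threshold = kp$threshold, n_test = sum(ok))
    }
  }
  list(records = dplyr::bind_rows(rows), regions = status)
}

#' Aggregate evaluation records
#'
#' Grouped means and standard deviations of AUC and Kappa over replicates
#' (and any other requested grouping), plus counts of records passing the
#' skill conventions AUC > 0.7 and Kappa > 0.4.
#'
#' @param records evaluation tibble from [cross_validate()] /
#'   [out_of_region()].
#' @param by character vector of grouping columns.
#' @return Tibble with per-group `mean_auc`, `sd_auc`, `mean_kappa`,
#'   `sd_kappa`, `n`, `n_auc_fair` (AUC > 0.7), `n_kappa_fair`
#'   (Kappa > 0.4).
#' @export
aggregate_evaluations <- function(records, by = c("dataset", "algorithm")) {
  if (!nrow(records)) stop("no records to aggregate", call. = FALSE)
  miss <- setdiff(by, names(records))
  if (length(miss)) stop("unknown grouping column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean_auc = mean(.data$auc),
      sd_auc = dplyr::coalesce(stats::sd(.data$auc), 0),
      mean_kappa = mean(.data$kappa),
      sd_kappa = dplyr::coalesce(stats::sd(.data$kappa), 0),
      n = dplyr::n(),
      n_auc_fair = sum(.data$auc > 0.7),
      n_kappa_fair = sum(.data$kappa > 0.4),
      .groups = "drop")
}
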