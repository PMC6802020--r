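# brute-force all-pairs AUC oracle
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# exhaustive-scan oracle for the max(sens+spec) threshold and Kappa
kappa_brute <- function(scores, labels) {
  best <- -Inf; best_t <- NA; n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  for (t in sort(unique(scores))) {
    pred <- scores >= t
    ss <- sum(pred & labels == 1) / n1 + sum(!pred & labels == 0) / n0
    if (ss > best + 1e-12) { best <- ss; best_t <- t }
  }
  pred <- scores >= best_t
  tp <- sum(pred & labels == 1); tn <- sum(!pred & labels == 0)
  fp <- sum(pred & labels == 0); fn <- sum(!pred & labels == 1)
  n <- length(labels)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  list(kappa = (po - pe) / (1 - pe), threshold = best_t)
}

test_that("AUC matches brute force, closed cases and monotone invariance", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:120, 1)
    scores <- round(runif(n), 2)  # rounded to force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels), auc_brute(scores, labels),
                 tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(auc(qlogis(pmin(pmax(scores, 0.01), 0.99)), labels),
                 auc(pmin(pmax(scores, 0.01), 0.99), labels),
                 tolerance = 1e-12)
  }
})

test_that("Kappa at the max sens+spec threshold matches the oracle", {
  # perfect separation
  k <- kappa_max_ss(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(k$kappa, 1)

  # engineered confusion TP 40 / TN 40 / FP 10 / FN 10 -> kappa 0.6
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 10), rep(0.1, 40))
  labels <- c(rep(1, 50), rep(0, 50))
  k2 <- kappa_max_ss(scores, labels)
  expect_equal(k2$kappa, 0.6, tolerance = 1e-12)
  expect_equal(k2$threshold, 0.9)

  set.seed(32)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ko <- kappa_brute(scores, labels)
    ki <- kappa_max_ss(scores, labels)
    expect_equal(ki$threshold, ko$threshold)
    expect_equal(ki$kappa, ko$kappa, tolerance = 1e-12)
    expect_lte(ki$kappa, 1)
  }
})

test_that("cross-validation partitions rows and scores sensibly", {
  tab <- quad_logistic_data(400, seed = 33)
  # constant (uninformative) model: AUC exactly 0.5 under tie handling
  const_fitter <- function(t) {
    m <- fit_glm(t, "cov_a", quadratic = FALSE)
    m$fit$coefficients[2] <- 0
    m
  }
  rec <- cross_validate(tab, const_fitter, folds = 5, seed = 34,
                        algorithm = "const")
  expect_equal(mean(rec$auc), 0.5, tolerance = 1e-9)
  expect_identical(nrow(rec), 5L)
  expect_equal(sum(rec$n_test), nrow(tab))  # folds partition the rows

  # informative GLM on a strong signal: high out-of-fold AUC
  tab_big <- quad_logistic_data(2000, beta = c(0, 2.5, -1.5, 1.5, -1),
                                seed = 38)
  rec2 <- cross_validate(tab_big, function(t) fit_glm(t), folds = 5,
                         seed = 35, algorithm = "glm")
  expect_gt(mean(rec2$auc), 0.85)
  expect_true(all(rec2$threshold >= 0 & rec2$threshold <= 1))
})

test_that("out-of-region validation enforces the eligibility threshold", {
  # two eligible regions + one with 24 presences (below the cut of 25)
  g <- grid_raster(matrix(0, 30, 30), xmin = 0, ymax = 30, cellsize = 1)
  regm <- matrix(3, 30, 30)
  regm[, 1:10] <- 1; regm[, 11:20] <- 2
  regions <- grid_raster(regm, xmin = 0, ymax = 30, cellsize = 1,
                         categorical = TRUE)
  set.seed(36)
  mkpts <- function(n, xlo, xhi) tibble::tibble(
    x = runif(n, xlo, xhi), y = runif(n, 0, 30))
  tab <- dplyr::bind_rows(
    dplyr::mutate(mkpts(40, 0, 10), response = 1),
    dplyr::mutate(mkpts(40, 10, 20), response = 1),
    dplyr::mutate(mkpts(24, 20, 30), response = 1),
    dplyr::mutate(mkpts(150, 0, 30), response = 0))
  tab$cov_a <- rnorm(nrow(tab)) + 2 * tab$response
  attr(tab, "covariates") <- "cov_a"
  res <- out_of_region(tab, regions, function(t)
    fit_glm(t, "cov_a", quadratic = FALSE), min_count = 25,
    algorithm = "glm")
  expect_identical(sort(unique(res$records$region)), c(1L, 2L))
  st <- res$regions
  expect_false(st$evaluated[st$region == 3])
  expect_identical(st$n_presence[st$region == 3], 24L)
  # each eligible region appears exactly once per replicate
  expect_identical(nrow(res$records), 2L)

  # identical environments across regions: transfer close to CV skill
  cvrec <- cross_validate(tab, function(t)
    fit_glm(t, "cov_a", quadratic = FALSE), folds = 5, seed = 37)
  expect_lt(abs(mean(res$records$auc) - mean(cvrec$auc)), 0.1)
})

test_that("aggregation reports grouped means, SDs and skill counts", {
  rec <- tibble::tibble(
    protocol = "cv", dataset = c("a", "a", "a"), strategy = "random",
    algorithm = "glm", replicate = 1:3, fold = 1, region = NA_integer_,
    auc = c(0.65, 0.72, 0.9), kappa = c(0.2, 0.45, 0.5),
    threshold = 0.5, n_test = 10)
  ag <- aggregate_evaluations(rec, by = "dataset")
  expect_equal(ag$mean_auc, mean(rec$auc))
  expect_identical(ag$n_auc_fair, 2L)
  expect_identical(ag$n_kappa_fair, 2L)

  single <- aggregate_evaluations(rec[1, ], by = "dataset")
  expect_equal(single$sd_auc, 0)
  expect_equal(single$mean_auc, 0.65)

  # oracle: brute-force groupwise recomputation
  rec2 <- dplyr::mutate(rec, dataset = c("a", "b", "a"))
  ag2 <- aggregate_evaluations(rec2, by = "dataset")
  expect_equal(ag2$mean_auc[ag2$dataset == "a"], mean(c(0.65, 0.9)))
  expect_error(aggregate_evaluations(rec, by = "nope"), "unknown grouping")
})
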