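sdm_fitted <- function(m) predict(m, m$training)

test_that("GLM recovers a null model and matches the likelihood identity", {
  set.seed(1)
  tab <- tibble::tibble(cov_a = rep(1, 200),
                        response = rep(c(0, 1), each = 100))
  m <- suppressWarnings(fit_glm(tab, "cov_a"))
  expect_equal(unique(round(suppressWarnings(sdm_fitted(m)), 10)), 0.5)

  tab2 <- quad_logistic_data(400, seed = 2)
  m2 <- fit_glm(tab2)
  # deviance = -2 logL with logL the direct Bernoulli sum
  p <- predict(m2, tab2)
  expect_equal(m2$deviance,
               -2 * sum(tab2$response * log(p) +
                          (1 - tab2$response) * log(1 - p)),
               tolerance = 1e-8)
  expect_true(all(p >= 0 & p <= 1))
  # predict on the training table reproduces the stored fit
  expect_equal(p, unname(fitted(m2$fit)), tolerance = 1e-12)
})

test_that("GLM matches an independent likelihood optimizer", {
  tab <- quad_logistic_data(500, seed = 3)
  m <- fit_glm(tab)
  # same design, maximized directly with optim (BFGS, analytic gradient)
  z1 <- scale(tab$cov_a); z2 <- scale(tab$cov_b)
  X <- cbind(1, z1, z1^2, z2, z2^2)
  y <- tab$response
  nll <- function(b) {
    eta <- X %*% b
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) -as.numeric(crossprod(X, y - plogis(X %*% b)))
  o <- optim(rep(0, 5), nll, gr, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-14))
  expect_equal(unname(coef(m$fit)), o$par, tolerance = 1e-5)
  expect_equal(m$logLik, -o$value, tolerance = 1e-7)
})

test_that("GLM recovers known quadratic-logistic coefficients within 3 SE", {
  beta <- c(0.5, 1.5, -1, 0.8, -0.6)
  tab <- quad_logistic_data(5000, beta = beta, seed = 4)
  m <- fit_glm(tab)
  td <- tidy(m)
  # translate truth to the standardized parametrization used internally
  mu1 <- mean(tab$cov_a); s1 <- sd(tab$cov_a)
  mu2 <- mean(tab$cov_b); s2 <- sd(tab$cov_b)
  truth <- c(beta[1] + beta[2] * mu1 + beta[3] * mu1^2 + beta[4] * mu2 +
               beta[5] * mu2^2,
             (beta[2] + 2 * beta[3] * mu1) * s1, beta[3] * s1^2,
             (beta[4] + 2 * beta[5] * mu2) * s2, beta[5] * s2^2)
  expect_true(all(abs(td$estimate - truth) < 3 * td$std.error))
})

test_that("response curves expose the fitted shapes", {
  tab <- quad_logistic_data(2000, beta = c(0, 1, -1.5, 0.1, 0), seed = 5)
  m <- fit_glm(tab)
  rc <- response_curve(m, "cov_a")
  expect_true(all(rc$value >= min(tab$cov_a) & rc$value <= max(tab$cov_a)))
  # negative quadratic on the logit: unimodal with an interior maximum
  peak <- which.max(rc$prediction)
  expect_gt(peak, 5)
  expect_lt(peak, 95)
  expect_error(response_curve(m, "nope"), "not in the model")

  # monotone single covariate: monotone prediction along its gradient
  tab_m <- quad_logistic_data(1500, beta = c(0, 2, 0, 0, 0), seed = 6)
  mm <- fit_glm(tab_m, "cov_a", quadratic = FALSE)
  rcm <- response_curve(mm, "cov_a")
  expect_true(all(diff(rcm$prediction) >= -1e-10))
})

test_that("BRT tuning selects by deviance with lexicographic tie-breaks", {
  # the selection rule itself, on a handcrafted table with exact ties
  cv_tab <- tibble::tibble(
    trees = c(500, 100, 100, 300), rate = c(0.01, 0.01, 0.005, 0.01),
    complexity = c(1, 2, 1, 1), cv_deviance = c(1.0, 1.0, 1.0, 1.2))
  sel <- sdmflow:::brt_select_setting(cv_tab)
  expect_equal(sel$trees, 100)
  expect_equal(sel$complexity, 1)
  expect_equal(sel$rate, 0.005)

  # pure-noise response: selected CV deviance within 2% of null deviance
  set.seed(7)
  tab <- tibble::tibble(cov_a = rnorm(400), cov_b = rnorm(400),
                        response = rbinom(400, 1, 0.5))
  attr(tab, "covariates") <- c("cov_a", "cov_b")
  grid <- list(trees = c(100, 200), rates = c(0.001, 0.01),
               complexities = 1:2)
  m <- tune_fit_brt(tab, grid = grid, folds = 5, seed = 8)
  null_dev_per_row <- -2 * mean(tab$response * log(mean(tab$response)) +
                                  (1 - tab$response) *
                                    log(1 - mean(tab$response)))
  expect_lt(abs(m$tuning$criterion - null_dev_per_row) / null_dev_per_row,
            0.02)

  # strong stepwise signal: CV deviance beats null by >= 20%
  set.seed(9)
  x <- rnorm(2000)
  tab2 <- tibble::tibble(cov_a = x,
                         response = rbinom(2000, 1,
                                           ifelse(x > 0, 0.9, 0.1)))
  attr(tab2, "covariates") <- "cov_a"
  m2 <- tune_fit_brt(tab2, grid = list(trees = c(100, 300, 500),
                                       rates = 0.01, complexities = 1:2),
                     folds = 5, seed = 10)
  null2 <- -2 * mean(tab2$response * log(mean(tab2$response)) +
                       (1 - tab2$response) * log(1 - mean(tab2$response)))
  expect_lt(m2$tuning$criterion, 0.8 * null2)
  # selected setting is a member of the searched grid
  expect_true(m2$tuning$selected$trees %in% c(100, 300, 500))
  expect_true(m2$tuning$selected$complexity %in% 1:2)

  # same seed reproduces the selection
  m2b <- tune_fit_brt(tab2, grid = list(trees = c(100, 300, 500),
                                        rates = 0.01, complexities = 1:2),
                      folds = 5, seed = 10)
  expect_identical(m2$tuning$selected, m2b$tuning$selected)
})

test_that("MaxEnt feature model shrinks to prevalence and ranks a logistic truth", {
  set.seed(11)
  tab <- quad_logistic_data(600, beta = c(-0.3, 1.2, 0, -0.8, 0), seed = 11)
  # extreme regularization: constant prediction at prevalence
  m_inf <- tune_fit_maxent(tab, reg_grid = 1e6, folds = 3, seed = 12)
  p <- predict(m_inf, tab)
  expect_true(all(abs(p - mean(tab$response)) < 1e-3))

  # linear-only features on a logistic truth: near-perfect ranking
  tab2 <- quad_logistic_data(2000, beta = c(0, 2, 0, -1.5, 0), seed = 13)
  truth_lp <- 2 * tab2$cov_a - 1.5 * tab2$cov_b
  m_lin <- tune_fit_maxent(tab2, features = "linear", seed = 14)
  rho <- cor(predict(m_lin, tab2), truth_lp, method = "spearman")
  expect_gte(rho, 0.9)
  expect_true(m_lin$tuning$selected$multiplier %in% seq(0.2, 5, 0.2))

  # full basis runs, stays in [0, 1], k counts nonzero weights + intercept
  m_full <- tune_fit_maxent(tab2, seed = 15)
  pf <- predict(m_full, tab2)
  expect_true(all(pf >= 0 & pf <= 1))
  expect_identical(m_full$k, sum(m_full$fit[-1] != 0) + 1L)
})

test_that("prediction contracts hold across engines and inputs", {
  w <- small_world(seed = 16)
  tab <- unbiased_table(w, n = 250, seed = 17)
  m <- fit_glm(tab)
  pr <- predict(m, w$stack)
  expect_s3_class(pr, "grid_raster")
  expect_true(all(pr$values >= 0 & pr$values <= 1, na.rm = TRUE))
  expect_equal(dim(pr), dim(w$stack$layers[[1]]))

  # nodata propagation: NA covariate cell -> NA prediction cell
  st2 <- w$stack
  st2$layers$cov1$values[5, 5] <- NA
  pr2 <- predict(m, st2)
  expect_true(is.na(pr2$values[5, 5]))
  expect_false(anyNA(pr2$values[-5, ]))

  expect_error(predict(m, tibble::tibble(cov1 = 1)), "missing covariate")

  # model JSON serialization round-trips the essentials
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  j <- jsonlite::read_json(f)
  expect_identical(j$algorithm, "GLM")
  expect_identical(sort(unlist(j$covariates)), sort(m$covariates))
  expect_equal(j$logLik, m$logLik, tolerance = 1e-9)
})
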