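test_that("metrics reproduces hand-computed values and guards degenerate input", {
  y <- c(0, 0, 2, 2)
  m <- metrics(y, rep(0, 4))
  expect_equal(m$r2, -1)
  expect_equal(m$rmse, sqrt(2))
  expect_equal(m$mae, 1)

  expect_equal(metrics(y, y)$r2, 1)
  expect_equal(metrics(y, y)$rmse, 0)
  expect_equal(metrics(y, rep(mean(y), 4))$r2, 0)
  expect_error(metrics(rep(1, 4), rnorm(4)), "zero variance")
  # training-mean convention is selectable
  expect_equal(metrics(y, rep(0, 4), center = 0)$r2, 1 - 8 / 8)
})

test_that("repeated k-fold CV is perfect on noiseless data and seed-stable", {
  prob <- make_linear_problem(n = 40, p = 4, support = 1:2,
                              beta = c(1, -1), noise_sd = 1e-13, seed = 5)
  cv <- repeated_kfold(ols_fit_spec(), prob$X, prob$y, repeats = 2, k = 5,
                       seed = 3)
  expect_equal(cv$fold_r2, rep(1, 10), tolerance = 1e-8)
  cv2 <- repeated_kfold(ols_fit_spec(), prob$X, prob$y, repeats = 2, k = 5,
                        seed = 3)
  expect_identical(cv2, cv)
  expect_true(cv$cv_r2_q025 <= cv$cv_r2_mean &&
                cv$cv_r2_mean <= cv$cv_r2_q975)
})

test_that("cross-validation never shows held-out rows to the fitting recipe", {
  prob <- make_linear_problem(n = 50, p = 6, seed = 9)
  leaks <- 0L
  spy_spec <- function(X, y) {
    seen <- rownames(X)
    mask <- stepwise_aic(X, y)$mask  # selection runs inside the fold
    model <- fit_ols(X[, mask, drop = FALSE], y)
    function(X_new) {
      if (length(intersect(rownames(X_new), seen)) > 0)
        leaks <<- leaks + 1L
      predict(model, X_new)
    }
  }
  repeated_kfold(spy_spec, prob$X, prob$y, repeats = 2, k = 5, seed = 4)
  expect_identical(leaks, 0L)
})

test_that("fold-level R2 disperses widely at small n, mirroring small-series CV", {
  fx <- study_shaped_fixture(seed = 33)
  std <- standardize(fx$dataset$X[, fx$dataset$true_support])
  cv <- repeated_kfold(ols_fit_spec(), std$X, fx$dataset$y,
                       repeats = 10, k = 5, seed = 8)
  expect_gt(IQR(cv$fold_r2), 0.2)
})

test_that("Y-randomization separates real signal from shuffled labels", {
  prob <- make_linear_problem(n = 60, p = 8, support = 1:3,
                              beta = c(1.5, 1.2, -1), noise_sd = 0.4,
                              seed = 21)
  yr <- y_randomization(ols_fit_spec(), prob$X, prob$y, B = 50, seed = 2)
  expect_equal(yr$p, 1 / 51)
  expect_gt(yr$r2_observed, 0.8)

  # B = 1 has two-point support
  yr1 <- y_randomization(ols_fit_spec(), prob$X, prob$y, B = 1, seed = 2)
  expect_true(yr1$p %in% c(0.5, 1))

  # the observed labels can never beat the +1 floor
  expect_gte(yr$p, 1 / 51)
})

test_that("leave-cluster-out scores each held-out cluster and flags tiny ones", {
  # four well-separated blobs with a shared linear signal
  set.seed(6)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8))
  X <- do.call(rbind, lapply(1:4, function(b)
    sweep(matrix(rnorm(30), 15, 2), 2, centers[b, ], "+")))
  colnames(X) <- c("d1", "d2")
  rownames(X) <- paste0("c", 1:60)
  y <- 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(60, 0, 0.3)
  lco <- leave_cluster_out(ols_fit_spec(), X, y, n_clusters = 4, seed = 3)
  expect_equal(nrow(lco), 4)
  expect_true(all(lco$r2 > 0))
  in_sample <- metrics(y, ols_fit_spec()(X, y)(X))$r2
  expect_lt(mean(lco$r2), in_sample)
  expect_identical(leave_cluster_out(ols_fit_spec(), X, y, n_clusters = 4,
                                     seed = 3), lco)

  # a cluster of 2 is reported but flagged unstable
  X2 <- rbind(X[1:28, ], matrix(c(50, 50, 50.5, 50.4), 2, 2, byrow = TRUE,
                                dimnames = list(c("o1", "o2"),
                                                c("d1", "d2"))))
  y2 <- c(y[1:28], 5, 5.1)
  lco2 <- leave_cluster_out(ols_fit_spec(), X2, y2, n_clusters = 3, seed = 1)
  tiny <- lco2[lco2$n_test == 2, ]
  expect_gte(nrow(tiny), 1)
  expect_true(all(tiny$unstable))
})

test_that("split conformal uses the (m+1)(1-alpha) order statistic", {
  set.seed(44)
  n <- 95
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(paste0("r", 1:n),
                                                  c("d1", "d2")))
  y <- rnorm(n)
  zero_spec <- function(X, y) function(X_new) rep(0, nrow(X_new))
  cf <- conformal_fit(zero_spec, X, y, alpha = 0.1, calib_fraction = 0.2,
                      seed = 7)
  expect_equal(cf$n_calibration, 19L)
  set.seed(7)
  calib <- sample.int(n, 19)
  expect_equal(cf$q_hat, sort(abs(y[calib]))[18])

  pr <- predict(cf, X[1:3, ])
  expect_equal(pr$upper - pr$lower, rep(2 * cf$q_hat, 3))
  expect_true(all(pr$lower <= pr$pred & pr$pred <= pr$upper))

  # vanishing noise collapses the intervals
  prob <- make_linear_problem(n = 60, p = 3, support = 1:2, beta = c(1, 1),
                              noise_sd = 1e-12, seed = 3)
  cf0 <- conformal_fit(ols_fit_spec(), prob$X, prob$y, seed = 5)
  expect_lt(cf0$q_hat, 1e-8)

  # too-small calibration set errors; infeasible alpha warns
  expect_error(conformal_fit(zero_spec, X[1:10, ], y[1:10]), "at least 5")
  expect_warning(cf_inf <- conformal_fit(zero_spec, X[1:40, ], y[1:40],
                                         alpha = 0.05),
                 "infinite")
  expect_identical(cf_inf$q_hat, Inf)
})

test_that("validation_report serializes the battery to JSON and TSV", {
  prob <- make_linear_problem(n = 50, p = 4, support = 1:2,
                              beta = c(1, -1), seed = 13)
  spec <- ols_fit_spec()
  cv <- repeated_kfold(spec, prob$X, prob$y, repeats = 2, k = 5, seed = 1)
  yr <- y_randomization(spec, prob$X, prob$y, B = 10, seed = 2)
  lco <- leave_cluster_out(spec, prob$X, prob$y, seed = 3)
  cf <- conformal_fit(spec, prob$X, prob$y, seed = 4)
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  validation_report(cv, yr, lco, cf, json_path = jp, tsv_path = tp)
  got <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(got$yrand_p, yr$p)
  expect_equal(nrow(got$lco_per_cluster), 4)
  expect_true(file.exists(tp))
})
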