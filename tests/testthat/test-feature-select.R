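test_that("adjusted_r2 matches the penalized formula and its limits", {
  expect_equal(adjusted_r2(0.5, 11, 1), 1 - 0.5 * 10 / 9)
  expect_equal(adjusted_r2(1, 30, 7), 1)
  # heavy penalty: k = n - 2 drags a modest R2 below itself
  expect_lt(adjusted_r2(0.6, 20, 18), 0.6)
  expect_error(adjusted_r2(0.5, 10, 9), "undefined")
})

test_that("ga_fitness equals adjusted R2 minus k/n, cross-checked against lm()", {
  prob <- make_linear_problem(seed = 2)
  mask <- seq_len(ncol(prob$X)) %in% c(1, 3, 5)
  f <- ga_fitness(mask, prob$X, prob$y)
  ref <- summary(lm(prob$y ~ prob$X[, mask]))
  expect_equal(f, ref$adj.r.squared - sum(mask) / length(prob$y),
               tolerance = 1e-12)
  expect_identical(ga_fitness(rep(FALSE, 8), prob$X, prob$y), -Inf)
  # duplicated column makes the fit singular -> sentinel
  Xs <- cbind(prob$X, dup = prob$X[, 1])
  expect_identical(ga_fitness(rep(TRUE, 9), Xs, prob$y), -Inf)
})

test_that("on noiseless data the true support beats every strict superset", {
  prob <- make_linear_problem(n = 60, p = 10, noise_sd = 1e-12, seed = 4)
  true_mask <- seq_len(10) %in% prob$support
  f_true <- ga_fitness(true_mask, prob$X, prob$y)
  for (extra in setdiff(seq_len(10), prob$support)) {
    sup <- true_mask
    sup[extra] <- TRUE
    expect_lt(ga_fitness(sup, prob$X, prob$y), f_true)
  }
})

test_that("ga_select is elitist, deterministic, and finds the exhaustive optimum", {
  prob <- make_linear_problem(n = 60, p = 8, seed = 6)
  oracle <- exhaustive_best_fitness(prob$X, prob$y)
  cfg <- ga_config(population_size = 60, max_generations = 60,
                   patience = 15, seed = 123)
  sel <- ga_select(prob$X, prob$y, cfg)
  expect_equal(sel$fitness, oracle$fitness, tolerance = 1e-10)
  expect_false(is.unsorted(sel$history))
  expect_equal(sel$fitness, ga_fitness(sel$mask, prob$X, prob$y))
  sel2 <- ga_select(prob$X, prob$y, cfg)
  expect_identical(sel2$mask, sel$mask)
  expect_identical(sel2$history, sel$history)
  expect_error(ga_select(prob$X, prob$y, ga_config(population_size = 1)),
               "population_size")
})

test_that("on pure noise the complexity penalty keeps the selection small", {
  n <- 60; p <- 8
  ks <- integer(20)
  gaps <- numeric(20)
  for (s in seq_len(20)) {
    set.seed(900 + s)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
    y <- rnorm(n)
    oracle <- exhaustive_best_fitness(X, y)
    sel <- ga_select(X, y, ga_config(population_size = 60,
                                     max_generations = 60, patience = 15,
                                     seed = s))
    ks[s] <- sum(sel$mask)
    gaps[s] <- oracle$fitness - sel$fitness
  }
  # the optimum on noise is itself small; GA stays near it
  expect_lte(median(ks), 3)
  expect_lte(median(gaps), 1e-10)
})

test_that("vif_filter removes collinear groups until all VIFs pass", {
  set.seed(30)
  # centered orthogonal columns: every VIF is exactly 1
  Q <- qr.Q(qr(scale(matrix(rnorm(200), 40, 5), scale = FALSE)))
  colnames(Q) <- paste0("q", 1:5)
  v <- vif_filter(Q)
  expect_true(all(v$mask))
  expect_equal(v$fitness, 1, tolerance = 1e-8)

  set.seed(8)
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("d", 1:4)))
  X <- cbind(X, s = X[, 1] + X[, 2])  # exact linear dependence
  out <- vif_filter(X, vif_max = 10)
  kept <- X[, out$mask, drop = FALSE]
  # recompute every VIF on the survivors independently
  for (j in seq_len(ncol(kept))) {
    r2 <- summary(lm(kept[, j] ~ kept[, -j]))$r.squared
    expect_lte(1 / (1 - r2), 10)
  }
  single <- vif_filter(X[, 1, drop = FALSE])
  expect_true(all(single$mask))
})

test_that("stepwise AIC starts null, recovers planted signal, never beats AIC backwards", {
  # y independent of X: a spurious column enters only when its score beats
  # the AIC penalty, so with 5 independent candidates the null survives at
  # about P(chisq_1 <= 2)^5 = 0.43, and the spurious model stays tiny
  ks <- vapply(seq_len(50), function(s) {
    set.seed(1200 + s)
    X <- matrix(rnorm(150 * 5), 150, 5, dimnames = list(NULL, paste0("d", 1:5)))
    sum(stepwise_aic(X, rnorm(150))$mask)
  }, numeric(1))
  null_rate <- pchisq(2, df = 1)^5
  expect_lt(abs(mean(ks == 0) - null_rate), 0.2)
  expect_lte(median(ks), 1)

  set.seed(31)
  X <- matrix(rnorm(100 * 6), 100, 6, dimnames = list(NULL, paste0("d", 1:6)))
  y <- X[, 1] - 0.8 * X[, 3] + rnorm(100, 0, 0.05)
  sw <- stepwise_aic(X, y)
  expect_true(all(c("d1", "d3") %in% names(sw$mask)[sw$mask]))

  # final AIC no worse than the null or the full model
  n <- 100
  aic_of <- function(mask) {
    rss <- sum(lm.fit(cbind(1, X[, mask, drop = FALSE]), y)$residuals^2)
    n * log(rss / n) + 2 * (sum(mask) + 1)
  }
  expect_lte(sw$fitness, aic_of(rep(FALSE, 6)) + 1e-10)
  expect_lte(sw$fitness, aic_of(rep(TRUE, 6)) + 1e-10)
})

test_that("BIC refit is at least as parsimonious as AIC and beats the null", {
  smaller <- vapply(seq_len(50), function(s) {
    set.seed(400 + s)
    X <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("d", 1:6)))
    y <- X[, 2] + rnorm(80, 0, 0.8)
    pool <- rep(TRUE, 6)
    k_aic <- sum(stepwise_aic(X, y)$mask)
    k_bic <- sum(bic_refit(X, y, pool)$mask)
    k_bic <= k_aic
  }, logical(1))
  expect_gte(mean(smaller), 0.9)

  set.seed(77)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y <- 2 * X[, 2] + rnorm(60, 0, 0.3)
  only <- bic_refit(X, y, seq_len(4) == 2)
  expect_equal(names(only$mask)[only$mask], "d2")
  n <- 60
  bic_null <- n * log(sum((y - mean(y))^2) / n) + log(n)
  expect_lte(only$fitness, bic_null)
  expect_error(bic_refit(X, y, rep(FALSE, 4)), "pool")
})

test_that("selection results serialize to JSON with the chosen names", {
  prob <- make_linear_problem(seed = 10)
  sel <- stepwise_aic(prob$X, prob$y)
  path <- tempfile(fileext = ".json")
  write_selection(sel, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$method, "stepwise")
  expect_setequal(got$selected, names(sel$mask)[sel$mask])
})
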