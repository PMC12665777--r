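test_that("standardize centers and scales with the n-1 convention and drops constants", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), d = c(0, 10, 20))
  expect_message(out <- standardize(X), "zero-variance")
  expect_equal(unname(out$X[, "a"]), c(-1, 0, 1))
  expect_false("b" %in% colnames(out$X))
  expect_equal(colMeans(out$X), c(a = 0, d = 0), tolerance = 1e-10)
  expect_equal(apply(out$X, 2, sd), c(a = 1, d = 1), tolerance = 1e-10)
  # idempotence: already-standardized input passes through
  again <- standardize(out$X)
  expect_equal(again$X, out$X, tolerance = 1e-10)
  expect_error(standardize(X[1, , drop = FALSE]), "2 rows")
})

test_that("apply_scaling projects into training space and validates columns", {
  set.seed(3)
  X <- matrix(rnorm(40, 10, 4), 10, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  out <- standardize(X)
  expect_equal(apply_scaling(X, out$scaling), out$X)
  # a row at the training means maps to the origin
  mu <- matrix(out$scaling$means, 1, dimnames = list(NULL, paste0("c", 1:4)))
  expect_equal(unname(drop(apply_scaling(mu, out$scaling))), rep(0, 4))
  expect_error(apply_scaling(X[, 1:3], out$scaling), "c4")
  # extra columns dropped with a message
  expect_message(apply_scaling(cbind(X, extra = 1:10), out$scaling),
                 "not in the scaling")
})

test_that("correlation_filter removes later members of high-correlation pairs", {
  set.seed(5)
  a <- rnorm(30)
  X <- cbind(a = a, b = a, c = rnorm(30))
  out <- correlation_filter(X)
  expect_equal(colnames(out), c("a", "c"))

  # orthogonal columns all survive
  Q <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  colnames(Q) <- paste0("q", 1:5)
  expect_equal(colnames(correlation_filter(Q)), colnames(Q))

  # 10 columns with 3 duplicated blocks: brute-force scan of the output
  base <- matrix(rnorm(30 * 7), 30, 7)
  X2 <- cbind(base, base[, 1] + rnorm(30, 0, 1e-4),
              base[, 3] + rnorm(30, 0, 1e-4),
              base[, 5] + rnorm(30, 0, 1e-4))
  colnames(X2) <- paste0("v", 1:10)
  out2 <- correlation_filter(X2, r_max = 0.95)
  cm <- abs(cor(out2))
  diag(cm) <- 0
  expect_true(all(cm <= 0.95))
  expect_equal(ncol(out2), 7)

  # appending an exact duplicate of a retained column leaves the result as-is
  dup <- cbind(out2, v1copy = out2[, 1])
  expect_equal(correlation_filter(dup, r_max = 0.95), out2)
})

test_that("variance_topk keeps the k largest-variance columns in original order", {
  X <- cbind(a = c(1, 2, 3), b = c(0, 2, 4), d = c(0, 3, 6))
  expect_identical(variance_topk(X, k = 50), X)
  expect_equal(colnames(variance_topk(X, k = 2)), c("b", "d"))
  # tie at the k-th variance: earlier column wins
  Xt <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), d = c(0, 5, 0))
  expect_equal(colnames(variance_topk(Xt, k = 2)), c("a", "d"))
})

test_that("stratified_split is exact, reproducible, and calibrated per bin", {
  ids <- paste0("c", 1:10)
  y <- seq(5, 9, length.out = 10)
  s <- stratified_split(ids, y, seed = 7)
  expect_length(s$train_ids, 7)
  expect_length(s$test_ids, 3)
  expect_setequal(c(s$train_ids, s$test_ids), ids)
  expect_length(intersect(s$train_ids, s$test_ids), 0)
  expect_identical(stratified_split(ids, y, seed = 7), s)

  # per-bin train fraction averages to 0.7 over 200 seeds
  set.seed(11)
  y2 <- rnorm(60)
  ids2 <- paste0("x", 1:60)
  brk <- quantile(y2, seq(0, 1, 0.2))
  bins <- cut(y2, brk, include.lowest = TRUE, labels = FALSE)
  fr <- vapply(1:200, function(sd) {
    sp <- stratified_split(ids2, y2, seed = sd)
    vapply(1:5, function(b) mean(ids2[bins == b] %in% sp$train_ids),
           numeric(1))
  }, numeric(5))
  expect_true(all(abs(rowMeans(fr) - 0.7) < 0.02))
})

test_that("preprocess runs the documented order and is a fixed point on training data", {
  fx <- study_shaped_fixture(seed = 21)
  prep <- preprocess(fx$dataset$X, fx$dataset$y, seed = 5)
  # re-projecting the raw training rows with the stored statistics is a
  # fixed point of the standardized training matrix
  raw_train <- fx$dataset$X[rownames(prep$X_train), ]
  expect_equal(suppressMessages(apply_scaling(raw_train, prep$scaling)),
               prep$X_train, tolerance = 1e-12)
  expect_equal(colMeans(prep$X_train), setNames(rep(0, ncol(prep$X_train)),
                                                colnames(prep$X_train)),
               tolerance = 1e-10)
  # injected near-duplicates were removed by the correlation filter
  dup_names <- names(fx$dataset$duplicate_of)
  expect_length(intersect(dup_names, prep$kept_columns), 0)
  # split covers everything exactly once
  expect_setequal(c(rownames(prep$X_train), rownames(prep$X_test)),
                  rownames(fx$dataset$X))
})

test_that("scaling parameters survive a JSON round trip exactly", {
  set.seed(9)
  X <- matrix(rnorm(30, 5, 2), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  sc <- standardize(X)$scaling
  path <- tempfile(fileext = ".json")
  write_scaling(sc, path)
  sc2 <- read_scaling(path)
  expect_identical(sc2$column_names, sc$column_names)
  expect_equal(sc2$means, sc$means)
  expect_equal(sc2$sds, sc$sds)
})
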