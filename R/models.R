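#' Fit an ordinary least squares model on standardized descriptors
#'
#' Solves the least-squares problem through the QR decomposition
#' (\code{lm.fit}) and stores the pieces needed downstream: named
#' coefficients, intercept, residual standard deviation (n - p - 1
#' denominator) and, optionally, the scaling parameters that map raw
#' descriptors into the model space. On standardized descriptors the
#' intercept equals the training mean of the response.
#'
#' @param X_train_std standardized training descriptor matrix (columns =
#'   the selected descriptors).
#' @param y_train training response (pIC50).
#' @param scaling optional \code{\link{scaling_params}} carried for
#'   screening-time normalization.
#' @return an object of class \code{qsar_lm}: \code{intercept},
#'   \code{coefficients} (named), \code{scaling}, \code{n_train}, \code{p},
#'   \code{residual_sd}, \code{fitted}, \code{residuals}.
#' @export
fit_ols <- function(X_train_std, y_train, scaling = NULL) {
  X <- as.matrix(X_train_std)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y_train) == n)
  if (n <= p + 1)
    stop("need n > p + 1 observations (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  design <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(design, y_train)
  if (fit$rank < p + 1L) {
    dep <- colnames(design)[is.na(fit$coefficients)]
    stop("rank-deficient design; linearly dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  coefs <- fit$coefficients
  structure(list(intercept = unname(coefs[1]),
                 coefficients = coefs[-1],
                 scaling = scaling,
                 n_train = n, p = p,
                 residual_sd = sqrt(sum(fit$residuals^2) / (n - p - 1)),
                 fitted = unname(fit$fitted.values),
                 residuals = unname(fit$residuals)),
            class = "qsar_lm")
}

#' Predict pIC50 from a linear QSAR model
#'
#' Computes \code{intercept + sum_j beta_j x_j} per row. The input must
#' already be on the standardized descriptor scale the model was fitted on
#' (use \code{\link{apply_scaling}} with the training statistics first).
#'
#' @param object a \code{qsar_lm} model.
#' @param newdata numeric matrix whose columns cover the model descriptors.
#' @param ... unused.
#' @return numeric vector of predicted pIC50, named by row when
#'   \code{newdata} has row names.
#' @export
predict.qsar_lm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  need <- names(object$coefficients)
  miss <- setdiff(need, colnames(X))
  if (length(miss))
    stop("prediction input is missing descriptor(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  drop(X[, need, drop = FALSE] %*% object$coefficients) + object$intercept
}

#' @export
print.qsar_lm <- function(x, ...) {
  cat("Linear QSAR model:", length(x$coefficients), "descriptor(s)\n")
  cat("  intercept:", format(x$intercept, digits = 6), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' The published eight-descriptor KRAS GA-MLR reference model
#'
#' Returns the GA-optimized multiple linear regression equation reported for
#' a 62-compound KRAS inhibitor series, operating on standardized
#' descriptors:
#' \deqn{pIC50 = 6.6791 - 0.5139 TASA + 0.8145 RDFE14 + 0.6494 grav
#'   + 0.00898 RDFE19 + 0.3118 PNSA3 - 0.3224 RDFM11 + 0.4943 RDFP9
#'   - 0.4546 RDFV14}
#' The original training-set scaling statistics were not published, so the
#' model ships without \code{scaling}: callers must supply descriptors
#' already standardized against their own training statistics (or attach
#' their own \code{\link{scaling_params}}).
#'
#' @return a \code{qsar_lm} with the published intercept and coefficients.
#' @examples
#' m <- published_kras_model()
#' z <- matrix(0, 1, 8, dimnames = list("q", names(m$coefficients)))
#' predict(m, z)  # the intercept, 6.6791
#' @export
published_kras_model <- function() {
  coefs <- c(TASA = -0.5139, RDFE14 = 0.8145, grav = 0.6494,
             RDFE19 = 0.00898, PNSA3 = 0.3118, RDFM11 = -0.3224,
             RDFP9 = 0.4943, RDFV14 = -0.4546)
  structure(list(intercept = 6.6791,
                 coefficients = coefs,
                 scaling = NULL,
                 n_train = 46L, p = 8L,
                 residual_sd = NA_real_,
                 fitted = NULL, residuals = NULL),
            class = "qsar_lm")
}

#' Fit a PLS1 regression with CV-selected component count
#'
#' NIPALS partial least squares for a single response. Components are
#' extracted sequentially from the (internally centered) training data; the
#' number of latent components is chosen to minimize 10-fold
#' cross-validated RMSE, with folds drawn from \code{seed}. At full rank the
#' PLS predictor coincides with OLS.
#'
#' @param X_train_std standardized training descriptor matrix.
#' @param y_train training response.
#' @param max_components maximum number of latent components to consider.
#' @param n_folds CV folds for component selection (default 10).
#' @param seed fold-assignment seed.
#' @return an object of class \code{pls_model}: \code{n_components},
#'   \code{coefficients}/\code{intercept} of the folded-back linear
#'   predictor at the chosen rank, \code{cv_rmse_per_component}.
#' @export
fit_pls <- function(X_train_std, y_train, max_components = NULL,
                    n_folds = 10, seed = 1L) {
  X <- as.matrix(X_train_std)
  n <- nrow(X)
  rank_max <- min(n - 1L, ncol(X))
  if (is.null(max_components)) max_components <- rank_max
  if (max_components < 1) stop("max_components must be >= 1", call. = FALSE)
  max_components <- min(max_components, rank_max)

  set.seed(seed)
  folds <- sample(rep_len(seq_len(min(n_folds, n)), n))
  cv_sse <- numeric(max_components)
  cv_n <- 0L
  for (f in sort(unique(folds))) {
    hold <- folds == f
    if (sum(hold) < 1L || sum(!hold) < 2L) next
    a_max <- min(max_components, sum(!hold) - 1L)
    fit <- .nipals_pls(X[!hold, , drop = FALSE], y_train[!hold], a_max)
    for (a in seq_len(max_components)) {
      aa <- min(a, a_max)
      pred <- drop(X[hold, , drop = FALSE] %*% fit$B[, aa]) + fit$b0[aa]
      cv_sse[a] <- cv_sse[a] + sum((y_train[hold] - pred)^2)
    }
    cv_n <- cv_n + sum(hold)
  }
  cv_rmse <- sqrt(cv_sse / cv_n)
  a_best <- which.min(cv_rmse)
  full <- .nipals_pls(X, y_train, max_components)
  structure(list(n_components = a_best,
                 intercept = full$b0[a_best],
                 coefficients = stats::setNames(full$B[, a_best],
                                                colnames(X)),
                 cv_rmse_per_component = cv_rmse,
                 seed = as.integer(seed)),
            class = "pls_model")
}

# NIPALS PLS1; returns per-rank regression vectors B (p x A) and intercepts
# b0 (length A) on the original (uncentered) scale.
.nipals_pls <- function(X, y, A) {
  xbar <- colMeans(X); ybar <- mean(y)
  E <- sweep(X, 2, xbar); f <- y - ybar
  p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A); qv <- numeric(A)
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pvec <- drop(crossprod(E, t)) / tt
    qa <- sum(t * f) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pvec; qv[a] <- qa
    a_used <- a
  }
  B <- matrix(0, p, A)
  for (a in seq_len(A)) {
    aa <- min(a, max(a_used, 1L))
    Wa <- W[, seq_len(aa), drop = FALSE]
    Pa <- P[, seq_len(aa), drop = FALSE]
    qa <- qv[seq_len(aa)]
    R <- Wa %*% solve(crossprod(Pa, Wa))
    B[, a] <- drop(R %*% qa)
  }
  list(B = B, b0 = ybar - drop(crossprod(B, xbar)))
}

#' Predict from a PLS model
#'
#' @param object a \code{pls_model}.
#' @param newdata matrix covering the model's descriptor columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, names(object$coefficients), drop = FALSE]
  drop(X %*% object$coefficients) + object$intercept
}

#' Fit tree-ensemble reference baselines
#'
#' Thin adapters over \pkg{randomForest} (500 trees) and \pkg{xgboost}
#' (squared-error loss, maximum depth 6, learning rate 0.1, 200 boosting
#' rounds) used only as comparative baselines for the linear models. Either
#' backend, if not installed, is skipped with a structured marker rather
#' than an error.
#'
#' @param X_train_std standardized training descriptor matrix.
#' @param y_train training response.
#' @param X_test_std optional test matrix for held-out metrics.
#' @param y_test optional test response.
#' @param n_trees random-forest tree count (default 500).
#' @param xgb_depth,xgb_eta,xgb_rounds gradient-boosting hyperparameters
#'   (defaults 6, 0.1, 200).
#' @param seed integer seed for both backends.
#' @return a list with elements \code{rf} and \code{xgb}, each either
#'   \code{list(skipped = TRUE, reason = ...)} or a list with
#'   \code{predict_train}, \code{predict_test} (or NULL) and \code{metrics}.
#' @export
fit_baselines <- function(X_train_std, y_train, X_test_std = NULL,
                          y_test = NULL, n_trees = 500, xgb_depth = 6,
                          xgb_eta = 0.1, xgb_rounds = 200, seed = 1L) {
  X <- as.matrix(X_train_std)
  out <- list()

  if (requireNamespace("randomForest", quietly = TRUE)) {
    set.seed(seed)
    rf <- randomForest::randomForest(X, y_train, ntree = n_trees)
    pr_tr <- unname(stats::predict(rf, X))
    pr_te <- if (!is.null(X_test_std))
      unname(stats::predict(rf, as.matrix(X_test_std))) else NULL
    out$rf <- list(skipped = FALSE, model = rf,
                   predict_train = pr_tr, predict_test = pr_te,
                   metrics = if (!is.null(y_test) && !is.null(pr_te))
                     metrics(y_test, pr_te) else NULL)
  } else {
    out$rf <- list(skipped = TRUE, reason = "randomForest not installed",
                   metrics = NULL)
  }

  if (requireNamespace("xgboost", quietly = TRUE)) {
    set.seed(seed)
    xgb <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", max_depth = xgb_depth,
                    eta = xgb_eta, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y_train, nthread = 1),
      nrounds = xgb_rounds, verbose = 0)
    pr_tr <- unname(stats::predict(xgb, X))
    pr_te <- if (!is.null(X_test_std))
      unname(stats::predict(xgb, as.matrix(X_test_std))) else NULL
    out$xgb <- list(skipped = FALSE, model = xgb,
                    predict_train = pr_tr, predict_test = pr_te,
                    metrics = if (!is.null(y_test) && !is.null(pr_te))
                      metrics(y_test, pr_te) else NULL)
  } else {
    out$xgb <- list(skipped = TRUE, reason = "xgboost not installed",
                    metrics = NULL)
  }
  out
}

#' Serialize a linear model to JSON
#'
#' Writes intercept, named coefficients, scaling reference and fit metadata
#' with full double precision, so a write/read round trip reproduces the
#' model exactly.
#'
#' @param model a \code{qsar_lm}.
#' @param path output path.
#' @param provenance optional named list recorded verbatim (method, seed...).
#' @return invisibly, \code{path}.
#' @export
write_model <- function(model, path, provenance = NULL) {
  obj <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              n_train = model$n_train, p = model$p,
              residual_sd = model$residual_sd,
              scaling = if (!is.null(model$scaling))
                list(column_names = model$scaling$column_names,
                     means = unname(model$scaling$means),
                     sds = unname(model$scaling$sds)) else NULL,
              provenance = provenance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a linear model from JSON
#'
#' @param path path written by \code{\link{write_model}}.
#' @return a \code{qsar_lm}.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaling <- if (!is.null(obj$scaling) && length(obj$scaling))
    scaling_params(obj$scaling$column_names, obj$scaling$means,
                   obj$scaling$sds) else NULL
  structure(list(intercept = obj$intercept,
                 coefficients = unlist(obj$coefficients),
                 scaling = scaling,
                 n_train = obj$n_train, p = obj$p,
                 residual_sd = if (is.null(obj$residual_sd)) NA_real_
                   else obj$residual_sd,
                 fitted = NULL, residuals = NULL),
            class = "qsar_lm")
}
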