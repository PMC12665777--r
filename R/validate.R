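#' Regression fit metrics
#'
#' R-squared (about the mean of the observed values), root mean squared
#' error, and mean absolute error.
#'
#' @param y_obs observed response.
#' @param y_pred predicted response, same length.
#' @param center optional reference mean for the R-squared total sum of
#'   squares; defaults to \code{mean(y_obs)}. Supplying the training mean
#'   gives the alternative external-validation convention.
#' @return a list of class \code{model_metrics}: \code{r2}, \code{rmse},
#'   \code{mae}, \code{n}.
#' @export
metrics <- function(y_obs, y_pred, center = NULL) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2)
  if (is.null(center)) center <- mean(y_obs)
  sstot <- sum((y_obs - center)^2)
  if (sstot == 0)
    stop("R-squared undefined: observed values have zero variance",
         call. = FALSE)
  err <- y_obs - y_pred
  structure(list(r2 = 1 - sum(err^2) / sstot,
                 rmse = sqrt(mean(err^2)),
                 mae = mean(abs(err)),
                 n = length(y_obs)),
            class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("n = %d  R2 = %.4f  RMSE = %.4f  MAE = %.4f\n",
              x$n, x$r2, x$rmse, x$mae))
  invisible(x)
}

#' A fit specification: OLS, with optional in-loop feature selection
#'
#' Validation routines re-run the whole modelling recipe on resampled data.
#' A fit spec is a function \code{f(X, y)} returning a prediction function
#' \code{g(X_new)}. This constructor builds the standard one: optional
#' feature selection (applied to the fold-training data only, so selection
#' never sees held-out rows) followed by OLS.
#'
#' @param selector \code{NULL} (use all columns) or a function
#'   \code{(X, y) -> logical mask} such as a wrapper around
#'   \code{\link{ga_select}} or \code{\link{stepwise_aic}}.
#' @return a fit-spec function.
#' @export
ols_fit_spec <- function(selector = NULL) {
  function(X, y) {
    X <- as.matrix(X)
    mask <- if (is.null(selector)) rep(TRUE, ncol(X)) else selector(X, y)
    model <- fit_ols(X[, mask, drop = FALSE], y)
    function(X_new) predict(model, as.matrix(X_new))
  }
}

#' Repeated k-fold cross-validation
#'
#' For each repeat a fresh seeded k-fold partition is drawn; the full fit
#' spec (including any feature selection it declares) is re-run on each
#' fold-training set and scored on the held-out fold. Per-fold R-squared and
#' RMSE are pooled across all repeats and summarized by their mean and
#' empirical 2.5\%/97.5\% quantiles. Folds that would hold out fewer than 2
#' points are merged into the next fold.
#'
#' @param fit_spec a function \code{(X, y) -> prediction function}.
#' @param X descriptor matrix, \code{y} response.
#' @param y numeric response.
#' @param repeats number of repeats (default 10).
#' @param k folds per repeat (default 5).
#' @param seed integer seed.
#' @return a list: \code{cv_r2_mean}, \code{cv_r2_q025}, \code{cv_r2_q975},
#'   \code{cv_rmse_mean}, \code{cv_rmse_q025}, \code{cv_rmse_q975},
#'   \code{fold_r2}, \code{fold_rmse}.
#' @export
repeated_kfold <- function(fit_spec, X, y, repeats = 10, k = 5, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= k)
  set.seed(seed)
  fold_r2 <- numeric(0); fold_rmse <- numeric(0)
  for (r in seq_len(repeats)) {
    folds <- sample(rep_len(seq_len(k), n))
    # merge undersized folds into a neighbour
    tab <- tabulate(folds, k)
    for (f in which(tab > 0 & tab < 2)) {
      tgt <- which.max(tab)
      folds[folds == f] <- tgt
      message("fold with < 2 held-out points merged into fold ", tgt)
    }
    for (f in sort(unique(folds))) {
      hold <- folds == f
      pred_fun <- fit_spec(X[!hold, , drop = FALSE], y[!hold])
      m <- metrics(y[hold], pred_fun(X[hold, , drop = FALSE]))
      fold_r2 <- c(fold_r2, m$r2)
      fold_rmse <- c(fold_rmse, m$rmse)
    }
  }
  q <- function(v, p) unname(stats::quantile(v, p, type = 7))
  list(cv_r2_mean = mean(fold_r2),
       cv_r2_q025 = q(fold_r2, 0.025), cv_r2_q975 = q(fold_r2, 0.975),
       cv_rmse_mean = mean(fold_rmse),
       cv_rmse_q025 = q(fold_rmse, 0.025), cv_rmse_q975 = q(fold_rmse, 0.975),
       fold_r2 = fold_r2, fold_rmse = fold_rmse)
}

#' Y-randomization (response permutation) test
#'
#' Refits the whole recipe on B permutations of the response and compares
#' the permuted training R-squared values with the observed one. The
#' empirical p-value uses the permutation-test +1 correction:
#' \code{p = (1 + #\{permuted R2 >= observed R2\}) / (B + 1)}, so its
#' minimum attainable value is \code{1/(B+1)}.
#'
#' @param fit_spec a function \code{(X, y) -> prediction function}.
#' @param X descriptor matrix.
#' @param y response.
#' @param B number of label shuffles (default 50).
#' @param seed integer seed.
#' @return a list: \code{p} (empirical p-value), \code{r2_observed},
#'   \code{r2_permuted} (length B).
#' @export
y_randomization <- function(fit_spec, X, y, B = 50, seed = 1L) {
  stopifnot(B >= 1)
  X <- as.matrix(X)
  train_r2 <- function(yy) {
    pred <- fit_spec(X, yy)(X)
    metrics(yy, pred)$r2
  }
  r2_obs <- train_r2(y)
  set.seed(seed)
  r2_perm <- vapply(seq_len(B), function(b) train_r2(sample(y)), numeric(1))
  list(p = (1 + sum(r2_perm >= r2_obs)) / (B + 1),
       r2_observed = r2_obs,
       r2_permuted = r2_perm)
}

#' Leave-cluster-out validation
#'
#' Clusters the compounds by k-means on the standardized descriptors and
#' holds out each whole cluster in turn, refitting on the remainder. This
#' emulates prediction on a novel chemical neighbourhood, a harder test than
#' random folds. Clusters holding out fewer than 3 points are flagged
#' unstable (their R-squared is reported but uninformative).
#'
#' @param fit_spec a function \code{(X, y) -> prediction function}.
#' @param X standardized descriptor matrix.
#' @param y response.
#' @param n_clusters number of k-means clusters (default 4).
#' @param seed integer seed (k-means initialization).
#' @return a data frame with one row per cluster: \code{cluster},
#'   \code{n_train}, \code{n_test}, \code{r2}, \code{rmse},
#'   \code{unstable}.
#' @export
leave_cluster_out <- function(fit_spec, X, y, n_clusters = 4, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= n_clusters)
  km <- NULL
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    km <- stats::kmeans(X, centers = n_clusters, nstart = 5)
    if (all(km$size > 0)) break
  }
  if (is.null(km) || any(km$size == 0))
    stop("k-means produced an empty cluster after re-seeding", call. = FALSE)
  rows <- lapply(seq_len(n_clusters), function(cl) {
    hold <- km$cluster == cl
    pred_fun <- fit_spec(X[!hold, , drop = FALSE], y[!hold])
    pred <- pred_fun(X[hold, , drop = FALSE])
    unstable <- sum(hold) < 3
    r2 <- rmse <- NA_real_
    if (sum(hold) >= 2 && stats::var(y[hold]) > 0) {
      m <- metrics(y[hold], pred)
      r2 <- m$r2; rmse <- m$rmse
    } else if (sum(hold) >= 1) {
      rmse <- sqrt(mean((y[hold] - pred)^2))
    }
    data.frame(cluster = cl, n_train = sum(!hold), n_test = sum(hold),
               r2 = r2, rmse = rmse, unstable = unstable)
  })
  do.call(rbind, rows)
}

#' Split conformal prediction calibration
#'
#' Splits the training data into a proper-training part and a calibration
#' part (default 80/20), fits the recipe on the proper-training part, and
#' takes \code{q_hat} as the \code{ceiling((m + 1) (1 - alpha))}-th smallest
#' absolute calibration residual (m = calibration size). Intervals are then
#' \code{prediction +/- q_hat}, with finite-sample marginal coverage at
#' least \code{1 - alpha} for exchangeable data. If the required order
#' statistic exceeds m, \code{q_hat} is \code{+Inf} with a warning.
#'
#' @param fit_spec a function \code{(X, y) -> prediction function}.
#' @param X_train training descriptor matrix.
#' @param y_train training response.
#' @param alpha nominal miscoverage (default 0.1).
#' @param calib_fraction fraction held out for calibration (default 0.2).
#' @param seed split seed.
#' @return an object of class \code{conformal_model}: \code{alpha},
#'   \code{q_hat}, \code{n_calibration}, \code{predict_fun}.
#' @export
conformal_fit <- function(fit_spec, X_train, y_train, alpha = 0.1,
                          calib_fraction = 0.2, seed = 1L) {
  X <- as.matrix(X_train)
  n <- nrow(X)
  m <- max(1L, round(calib_fraction * n))
  if (m < 5)
    stop("calibration set must have at least 5 points (got ", m, ")",
         call. = FALSE)
  set.seed(seed)
  calib <- sample.int(n, m)
  is_cal <- seq_len(n) %in% calib
  pred_fun <- fit_spec(X[!is_cal, , drop = FALSE], y_train[!is_cal])
  scores <- sort(abs(y_train[is_cal] - pred_fun(X[is_cal, , drop = FALSE])))
  idx <- ceiling((m + 1) * (1 - alpha))
  if (idx > m) {
    warning("calibration set too small for alpha = ", alpha,
            "; intervals are infinite")
    q_hat <- Inf
  } else q_hat <- unname(scores[idx])
  structure(list(alpha = alpha, q_hat = q_hat, n_calibration = m,
                 predict_fun = pred_fun, seed = as.integer(seed)),
            class = "conformal_model")
}

#' Conformal prediction intervals
#'
#' @param object a \code{conformal_model}.
#' @param newdata descriptor matrix on the model scale.
#' @param ... unused.
#' @return a data frame: \code{pred}, \code{lower}, \code{upper}.
#' @export
predict.conformal_model <- function(object, newdata, ...) {
  pred <- object$predict_fun(as.matrix(newdata))
  data.frame(pred = pred,
             lower = pred - object$q_hat,
             upper = pred + object$q_hat)
}

#' Assemble and serialize a validation report
#'
#' Collates cross-validation, Y-randomization, leave-cluster-out and
#' conformal summaries into one list and optionally writes JSON and TSV
#' renderings.
#'
#' @param cv result of \code{\link{repeated_kfold}}.
#' @param yrand result of \code{\link{y_randomization}}.
#' @param lco result of \code{\link{leave_cluster_out}}.
#' @param conformal a \code{conformal_model} (or \code{NULL}).
#' @param conformal_coverage optional empirical coverage measured on a test
#'   set.
#' @param json_path,tsv_path optional output paths.
#' @return the report list, invisibly when writing.
#' @export
validation_report <- function(cv = NULL, yrand = NULL, lco = NULL,
                              conformal = NULL, conformal_coverage = NULL,
                              json_path = NULL, tsv_path = NULL) {
  rep <- list(
    cv_r2_mean = cv$cv_r2_mean, cv_r2_q025 = cv$cv_r2_q025,
    cv_r2_q975 = cv$cv_r2_q975, cv_rmse_mean = cv$cv_rmse_mean,
    yrand_p = yrand$p,
    lco_per_cluster = lco,
    conformal_width = if (!is.null(conformal)) 2 * conformal$q_hat else NULL,
    conformal_coverage = conformal_coverage)
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows", null = "null")
  if (!is.null(tsv_path)) {
    scalars <- rep[!vapply(rep, is.data.frame, logical(1))]
    scalars <- scalars[!vapply(scalars, is.null, logical(1))]
    utils::write.table(
      data.frame(statistic = names(scalars),
                 value = unlist(scalars, use.names = FALSE)),
      tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (is.null(json_path) && is.null(tsv_path)) rep else invisible(rep)
}
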