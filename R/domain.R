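#' Mahalanobis-distance applicability domain
#'
#' Computes the squared Mahalanobis distance of each query compound from the
#' training-set centroid, \code{D2 = (x - mu)' Sigma^{-1} (x - mu)}, with
#' \code{mu} the training column means and \code{Sigma} the training sample
#' covariance. For multivariate-Gaussian descriptors D2 is chi-squared
#' distributed with p degrees of freedom, so the default in-domain threshold
#' is the 95th percentile of chi-squared(p); a fixed override (e.g. 15.0)
#' reproduces screening pipelines that apply a hard cutoff. A singular
#' covariance falls back to a small ridge (1e-8 of the mean diagonal),
#' with a message.
#'
#' @param X_train_std standardized training descriptor matrix.
#' @param X_query_std query matrix with the same columns.
#' @param df_override degrees of freedom for the chi-squared threshold
#'   (default: number of descriptors).
#' @param threshold_override fixed D2 cutoff replacing the analytic
#'   threshold.
#' @param level chi-squared percentile for the analytic threshold
#'   (default 0.95).
#' @return a list of class \code{ad_report}: per-compound data frame
#'   \code{table} (\code{id}, \code{mahalanobis_d2}, \code{inside_md}) and
#'   globals \code{md_threshold}, \code{coverage}.
#' @export
mahalanobis_doa <- function(X_train_std, X_query_std, df_override = NULL,
                            threshold_override = NULL, level = 0.95) {
  Xt <- as.matrix(X_train_std)
  Xq <- as.matrix(X_query_std)
  if (ncol(Xq) != ncol(Xt) ||
      (!is.null(colnames(Xq)) && !is.null(colnames(Xt)) &&
       !identical(colnames(Xq), colnames(Xt))))
    stop("query descriptor columns do not match the training matrix",
         call. = FALSE)
  mu <- colMeans(Xt)
  Sigma <- stats::cov(Xt)
  ok <- tryCatch({ solve(Sigma); TRUE }, error = function(e) FALSE)
  if (!ok) {
    message("singular training covariance; adding ridge")
    Sigma <- Sigma + diag(1e-8 * mean(diag(Sigma)), ncol(Sigma))
  }
  d2 <- stats::mahalanobis(Xq, center = mu, cov = Sigma)
  df <- if (is.null(df_override)) ncol(Xt) else df_override
  thr <- if (is.null(threshold_override))
    stats::qchisq(level, df = df) else threshold_override
  inside <- d2 <= thr
  structure(list(
    table = data.frame(id = rownames(Xq) %||% seq_len(nrow(Xq)),
                       mahalanobis_d2 = unname(d2),
                       inside_md = unname(inside)),
    md_threshold = thr, df = df,
    coverage = mean(inside)),
    class = "ad_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leverage threshold for the Williams plot
#'
#' The conventional warning leverage \code{h* = 3 (p + 1) / n}, three times
#' the mean training leverage of a p-descriptor linear model fitted on n
#' compounds.
#'
#' @param p number of descriptors in the model.
#' @param n number of training compounds.
#' @return the threshold h*.
#' @examples
#' leverage_threshold(15, 46)  # 48/46 = 1.043
#' @export
leverage_threshold <- function(p, n) 3 * (p + 1) / n

#' Williams-plot applicability domain
#'
#' Computes leverages \code{h_i = x_i' (X'X)^{-1} x_i} on the
#' intercept-augmented training design (queries are projected through the
#' same matrix), standardized residuals
#' \code{residual / residual_scale}, and the in-domain box: leverage at most
#' \code{h* = 3(p+1)/n} and absolute standardized residual at most 3.
#'
#' @param X_train_std standardized training descriptor matrix.
#' @param X_test_std test/query matrix with the same columns (may be
#'   \code{NULL}).
#' @param residuals_train training residuals.
#' @param residuals_test test residuals (may be \code{NULL} when unknown).
#' @param residual_scale scale for standardizing residuals; default is the
#'   training residual SD with \code{n - p - 1} denominator.
#' @return a list of class \code{williams_ad}: \code{train} and \code{test}
#'   data frames (\code{id}, \code{leverage}, \code{std_residual},
#'   \code{inside_williams}), plus \code{h_star}, \code{coverage_train},
#'   \code{coverage_test}.
#' @export
williams_ad <- function(X_train_std, X_test_std = NULL,
                        residuals_train = NULL, residuals_test = NULL,
                        residual_scale = NULL) {
  Xt <- as.matrix(X_train_std)
  n <- nrow(Xt); p <- ncol(Xt)
  D <- cbind(1, Xt)
  qrD <- qr(D)
  if (qrD$rank < p + 1L)
    stop("rank-deficient training design; leverages undefined",
         call. = FALSE)
  XtXinv <- chol2inv(qr.R(qrD))
  lev <- function(M) rowSums((cbind(1, M) %*% XtXinv) * cbind(1, M))
  h_train <- lev(Xt)
  h_star <- leverage_threshold(p, n)
  if (is.null(residual_scale)) {
    if (is.null(residuals_train))
      stop("supply residuals_train or residual_scale", call. = FALSE)
    residual_scale <- sqrt(sum(residuals_train^2) / (n - p - 1))
  }
  box <- function(h, r) {
    sr <- if (is.null(r)) rep(NA_real_, length(h)) else r / residual_scale
    inside <- h <= h_star & (is.na(sr) | abs(sr) <= 3)
    list(sr = sr, inside = inside)
  }
  btr <- box(h_train, residuals_train)
  train_df <- data.frame(id = rownames(Xt) %||% seq_len(n),
                         leverage = unname(h_train),
                         std_residual = unname(btr$sr),
                         inside_williams = unname(btr$inside))
  test_df <- NULL; cov_test <- NA_real_
  if (!is.null(X_test_std)) {
    Xq <- as.matrix(X_test_std)[, colnames(Xt), drop = FALSE]
    h_test <- lev(Xq)
    bte <- box(h_test, residuals_test)
    test_df <- data.frame(id = rownames(Xq) %||% seq_len(nrow(Xq)),
                          leverage = unname(h_test),
                          std_residual = unname(bte$sr),
                          inside_williams = unname(bte$inside))
    cov_test <- mean(bte$inside)
  }
  structure(list(train = train_df, test = test_df,
                 h_star = h_star,
                 residual_scale = residual_scale,
                 coverage_train = mean(btr$inside),
                 coverage_test = cov_test),
            class = "williams_ad")
}

#' Metrics stratified by applicability-domain membership
#'
#' Computes fit metrics for the whole set and separately for the inside-
#' and outside-domain strata. Strata with fewer than 3 compounds are
#' reported as counts only (their R-squared would be meaningless).
#'
#' @param y_obs observed response.
#' @param y_pred predicted response.
#' @param inside_flags logical vector aligned with the observations.
#' @return a data frame with rows \code{all}, \code{inside}, \code{outside}:
#'   \code{n}, \code{r2}, \code{rmse}, \code{mae} (NA where suppressed).
#' @export
ad_stratified_metrics <- function(y_obs, y_pred, inside_flags) {
  stopifnot(length(y_obs) == length(y_pred),
            length(y_obs) == length(inside_flags))
  one <- function(sel, label) {
    n <- sum(sel)
    if (n >= 3 && stats::var(y_obs[sel]) > 0) {
      m <- metrics(y_obs[sel], y_pred[sel])
      data.frame(stratum = label, n = n, r2 = m$r2, rmse = m$rmse,
                 mae = m$mae)
    } else {
      data.frame(stratum = label, n = n, r2 = NA_real_, rmse = NA_real_,
                 mae = NA_real_)
    }
  }
  rbind(one(rep(TRUE, length(y_obs)), "all"),
        one(inside_flags, "inside"),
        one(!inside_flags, "outside"))
}

#' Write an AD report as TSV (per compound) plus JSON globals
#'
#' @param report a \code{ad_report} or \code{williams_ad}.
#' @param tsv_path per-compound table output.
#' @param json_path globals output.
#' @return invisibly, \code{tsv_path}.
#' @export
write_ad_report <- function(report, tsv_path, json_path = NULL) {
  tab <- if (inherits(report, "williams_ad")) {
    rbind(cbind(set = "train", report$train),
          if (!is.null(report$test)) cbind(set = "test", report$test))
  } else report$table
  utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(json_path)) {
    globals <- report[!vapply(report, is.data.frame, logical(1))]
    globals <- globals[!vapply(globals, is.null, logical(1))]
    jsonlite::write_json(globals, json_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(tsv_path)
}
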