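#' Permutation feature importance (MSE increase)
#'
#' For each descriptor, shuffles that column within the data, recomputes the
#' model's mean squared error, and reports the average increase over the
#' baseline MSE across \code{n_repeats} seeded shuffles. Features the model
#' ignores score near zero; features carrying signal score positive.
#'
#' @param model_predict a prediction function \code{(X) -> numeric}, e.g.
#'   \code{function(X) predict(model, X)}.
#' @param X descriptor matrix.
#' @param y observed response.
#' @param n_repeats shuffles per descriptor (default 20).
#' @param seed integer seed.
#' @return a data frame of class \code{importance_table}, one row per
#'   descriptor: \code{descriptor}, \code{importance} (mean MSE increase),
#'   \code{rank}; attributes \code{n_repeats}, \code{seed}.
#' @export
permutation_importance <- function(model_predict, X, y, n_repeats = 20,
                                   seed = 1L) {
  X <- as.matrix(X)
  base_mse <- mean((y - model_predict(X))^2)
  set.seed(seed)
  imp <- vapply(seq_len(ncol(X)), function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      mean((y - model_predict(Xp))^2) - base_mse
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(descriptor = colnames(X), importance = imp)
  out$rank <- rank(-out$importance, ties.method = "first")
  attr(out, "n_repeats") <- n_repeats
  attr(out, "seed") <- seed
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Exact additive attribution for a linear model
#'
#' For an additive model with independent features the Shapley value of
#' descriptor j on compound i has the closed form
#' \code{phi_ij = beta_j (x_ij - background_mean_j)}, with the base value
#' the prediction at the background point. No sampling is involved and the
#' attributions satisfy local accuracy exactly:
#' \code{base_value + sum_j phi_ij = prediction_i}.
#'
#' @param model a \code{qsar_lm}.
#' @param X_std matrix on the model's standardized scale.
#' @param background_means named background vector (default: all zeros, the
#'   training means on the standardized scale).
#' @return a list of class \code{attribution_matrix}: \code{phi} (compounds
#'   x descriptors), \code{base_value}, \code{predictions}.
#' @export
linear_attribution <- function(model, X_std, background_means = NULL) {
  X <- as.matrix(X_std)
  nm <- names(model$coefficients)
  X <- X[, nm, drop = FALSE]
  if (is.null(background_means))
    background_means <- stats::setNames(rep(0, length(nm)), nm)
  bg <- background_means[nm]
  phi <- sweep(X, 2, bg, "-") %*% diag(model$coefficients, length(nm))
  colnames(phi) <- nm
  base <- model$intercept + sum(model$coefficients * bg)
  structure(list(phi = phi,
                 base_value = base,
                 predictions = base + rowSums(phi)),
            class = "attribution_matrix")
}

#' Top-k descriptors by importance
#'
#' Orders descriptors by decreasing importance (for an attribution matrix,
#' by mean absolute attribution) and returns the first k names. Ties break
#' alphabetically; \code{k} larger than the number of descriptors returns
#' the full list.
#'
#' @param table an \code{importance_table} or \code{attribution_matrix}.
#' @param k number of descriptors to return (default 8).
#' @return character vector of descriptor names.
#' @export
rank_top_k <- function(table, k = 8) {
  if (inherits(table, "attribution_matrix")) {
    score <- colMeans(abs(table$phi))
    nm <- colnames(table$phi)
  } else {
    score <- table$importance
    nm <- table$descriptor
  }
  ord <- order(-score, nm)
  nm[ord][seq_len(min(k, length(nm)))]
}
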