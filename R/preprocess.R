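#' Scaling parameters (training means and standard deviations)
#'
#' Constructor for the per-descriptor centering/scaling statistics estimated
#' on a training set and reused verbatim for test and screening data, so that
#' query compounds are projected into the model's standardized descriptor
#' space.
#'
#' @param column_names character vector of descriptor names.
#' @param means,sds numeric vectors aligned with \code{column_names};
#'   \code{sds} must be strictly positive.
#' @return an object of class \code{scaling_params}.
#' @export
scaling_params <- function(column_names, means, sds) {
  stopifnot(length(column_names) == length(means),
            length(means) == length(sds))
  if (any(!is.finite(sds) | sds <= 0))
    stop("scaling SDs must be strictly positive", call. = FALSE)
  structure(list(column_names = as.character(column_names),
                 means = stats::setNames(as.numeric(means), column_names),
                 sds = stats::setNames(as.numeric(sds), column_names)),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat("Scaling parameters for", length(x$column_names), "descriptor(s)\n")
  invisible(x)
}

#' Standardize a descriptor matrix
#'
#' Centers each column to zero mean and scales to unit sample standard
#' deviation (n-1 denominator). Zero-variance columns cannot be scaled and
#' are dropped first with a message.
#'
#' @param X numeric descriptor matrix (compounds x descriptors).
#' @return a list with \code{X} (the standardized matrix) and \code{scaling}
#'   (a \code{\link{scaling_params}} object for the retained columns).
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L)
    stop("standardize needs at least 2 rows", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    message("dropping ", sum(zero), " zero-variance column(s): ",
            paste(colnames(X)[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  if (ncol(X) == 0L) stop("no columns left to standardize", call. = FALSE)
  means <- colMeans(X)
  params <- scaling_params(colnames(X), means, sds)
  list(X = apply_scaling(X, params), scaling = params)
}

#' Apply stored scaling parameters to a descriptor matrix
#'
#' Projects new data into the training standardized space using the stored
#' training means and SDs: \code{(x - mean) / sd} column-wise. Columns of
#' \code{X} not named in \code{params} are dropped with a message; columns
#' required by \code{params} but absent from \code{X} are an error.
#'
#' @param X numeric matrix containing at least the columns in \code{params}.
#' @param params a \code{\link{scaling_params}} object.
#' @return the standardized matrix with columns ordered as in \code{params}.
#' @export
apply_scaling <- function(X, params) {
  stopifnot(inherits(params, "scaling_params"))
  X <- as.matrix(X)
  need <- params$column_names
  miss <- setdiff(need, colnames(X))
  if (length(miss))
    stop("descriptor matrix is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(colnames(X), need)
  if (length(extra))
    message("dropping ", length(extra),
            " column(s) not in the scaling parameters")
  X <- X[, need, drop = FALSE]
  sweep(sweep(X, 2, params$means, "-"), 2, params$sds, "/")
}

#' Remove highly correlated descriptors
#'
#' Greedy pairwise Pearson correlation filter: pairs are scanned in column
#' order and, when a pair exceeds \code{r_max} in absolute correlation, the
#' later column is dropped. After filtering, no retained pair has
#' \code{|r| > r_max}.
#'
#' @param X numeric descriptor matrix with at least 2 rows.
#' @param r_max absolute Pearson correlation threshold (default 0.95).
#' @return the filtered matrix.
#' @export
correlation_filter <- function(X, r_max = 0.95) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L)
  p <- ncol(X)
  if (p < 2L) return(X)
  cm <- abs(suppressWarnings(stats::cor(X)))
  cm[!is.finite(cm)] <- 0  # zero-variance columns correlate with nothing
  keep <- rep(TRUE, p)
  for (i in seq_len(p - 1L)) {
    if (!keep[i]) next
    for (j in seq.int(i + 1L, p)) {
      if (keep[j] && cm[i, j] > r_max) keep[j] <- FALSE
    }
  }
  X[, keep, drop = FALSE]
}

#' Keep the top-k descriptors by variance
#'
#' Retains the \code{k} columns with the largest sample variance, preserving
#' the original column order. Ties at the k-th variance are resolved in
#' favour of the earlier column. Applied before standardization (afterwards
#' every variance is 1 and the ranking is vacuous).
#'
#' @param X numeric descriptor matrix.
#' @param k number of columns to keep (default 50).
#' @return the reduced matrix (identity when \code{ncol(X) <= k}).
#' @export
variance_topk <- function(X, k = 50) {
  X <- as.matrix(X)
  stopifnot(k >= 1)
  if (ncol(X) <= k) return(X)
  v <- apply(X, 2, stats::var)
  ord <- order(-v, seq_along(v))  # earlier column wins ties
  keep <- sort(ord[seq_len(k)])
  X[, keep, drop = FALSE]
}

#' Stratified train/test split on a continuous response
#'
#' Bins the response into quantile bins and samples a fixed fraction of each
#' bin into the training set, so the two partitions have matching activity
#' distributions. Reproducible given \code{seed}.
#'
#' @param ids character vector of compound ids.
#' @param y numeric response (pIC50) aligned with \code{ids}.
#' @param train_fraction fraction assigned to training (default 0.7).
#' @param n_bins number of quantile bins (default 5).
#' @param seed integer seed for the sampling.
#' @return a list of class \code{split_result} with \code{train_ids},
#'   \code{test_ids}, \code{seed}, \code{train_fraction}.
#' @export
stratified_split <- function(ids, y, train_fraction = 0.7, n_bins = 5,
                             seed = 1L) {
  stopifnot(length(ids) == length(y), train_fraction > 0, train_fraction < 1)
  n <- length(ids)
  if (n < n_bins)
    stop("need at least n_bins = ", n_bins, " observations", call. = FALSE)
  brk <- unique(stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(y, breaks = brk, include.lowest = TRUE, labels = FALSE)
  set.seed(seed)
  # per-bin quotas by floor + largest remainder (random tie-break), so the
  # total training size is exactly round(train_fraction * n)
  lev <- sort(unique(bins))
  sizes <- vapply(lev, function(b) sum(bins == b), integer(1))
  quota <- train_fraction * sizes
  n_tr <- pmin(floor(quota), sizes)
  leftover <- round(train_fraction * n) - sum(n_tr)
  if (leftover > 0) {
    room <- sizes - n_tr
    pick <- order(-(quota - floor(quota)), sample.int(length(lev)))
    for (b in pick) {
      if (leftover == 0L) break
      if (room[b] > 0L) { n_tr[b] <- n_tr[b] + 1L; leftover <- leftover - 1L }
    }
  }
  train <- unlist(lapply(seq_along(lev), function(i) {
    members <- ids[bins == lev[i]]
    sample(members, n_tr[i])
  }), use.names = FALSE)
  structure(list(train_ids = train,
                 test_ids = setdiff(ids, train),
                 seed = as.integer(seed),
                 train_fraction = train_fraction),
            class = "split_result")
}

#' Full preprocessing pipeline
#'
#' Applies the fixed preprocessing order: drop zero-variance columns,
#' correlation filter on the raw scale, top-k variance filter on the raw
#' scale, then standardization re-estimated on the surviving columns, then
#' the stratified split. Variance ranking is meaningful only before scaling,
#' which is why standardization comes last.
#'
#' @param X raw numeric descriptor matrix.
#' @param y numeric response aligned with \code{rownames(X)}.
#' @param r_max correlation threshold (default 0.95).
#' @param top_k variance filter size (default 50).
#' @param train_fraction,n_bins,seed passed to \code{\link{stratified_split}}.
#' @return list with \code{X_train}, \code{X_test} (standardized with the
#'   training statistics), \code{y_train}, \code{y_test}, \code{scaling},
#'   \code{split}, \code{kept_columns}.
#' @export
preprocess <- function(X, y, r_max = 0.95, top_k = 50,
                       train_fraction = 0.7, n_bins = 5, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(!is.null(rownames(X)), length(y) == nrow(X))
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0 & is.finite(sds), drop = FALSE]
  X <- correlation_filter(X, r_max = r_max)
  X <- variance_topk(X, k = top_k)
  split <- stratified_split(rownames(X), y, train_fraction = train_fraction,
                            n_bins = n_bins, seed = seed)
  tr <- rownames(X) %in% split$train_ids
  std <- standardize(X[tr, , drop = FALSE])
  names(y) <- rownames(X)
  list(X_train = std$X,
       X_test = apply_scaling(X[!tr, , drop = FALSE], std$scaling),
       y_train = y[rownames(X)[tr]],
       y_test = y[rownames(X)[!tr]],
       scaling = std$scaling,
       split = split,
       kept_columns = colnames(std$X))
}

#' Write scaling parameters to a JSON sidecar
#'
#' @param params a \code{\link{scaling_params}} object.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_scaling <- function(params, path) {
  stopifnot(inherits(params, "scaling_params"))
  jsonlite::write_json(
    list(column_names = params$column_names,
         means = unname(params$means),
         sds = unname(params$sds)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read scaling parameters from a JSON sidecar
#'
#' @param path path written by \code{\link{write_scaling}}.
#' @return a \code{\link{scaling_params}} object.
#' @export
read_scaling <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaling_params(obj$column_names, obj$means, obj$sds)
}
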