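#' Specification for a synthetic QSAR dataset
#'
#' Describes a simulated compound series with the statistical structure a
#' small-series QSAR analysis assumes: a modest number of compounds, a
#' wider block-correlated descriptor table on heterogeneous raw scales, a
#' sparse linear activity signal on a few descriptors, Gaussian noise, and
#' a handful of near-duplicate descriptor pairs (|r| > 0.95) of the kind
#' produced by adjacent radial-distribution shells.
#'
#' @param n_compounds number of compounds (default 62).
#' @param n_descriptors total descriptor count including near-duplicate
#'   columns (default 50).
#' @param n_informative number of descriptors carrying signal (default 8).
#' @param beta \code{"published"} (coefficient magnitudes and signs of the
#'   built-in KRAS reference equation), or a numeric vector of length
#'   \code{n_informative} giving coefficients on the standardized scale.
#' @param noise_sd Gaussian noise SD on the pIC50 scale (default 0.95,
#'   which puts the in-sample OLS R-squared near 0.72 under the default
#'   signal).
#' @param n_correlated_pairs near-duplicate descriptor pairs injected
#'   (default 5).
#' @param y_center mean pIC50 (default 6.7).
#' @param block_size,block_r size and within-block correlation of the
#'   non-informative descriptor blocks (defaults 5 and 0.5).
#' @param lognormal_marginals if \code{TRUE}, descriptor marginals are
#'   log-normal instead of Gaussian (a skewness stress test).
#' @param seed integer seed.
#' @return a list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_compounds = 62, n_descriptors = 50,
                           n_informative = 8, beta = "published",
                           noise_sd = 0.95, n_correlated_pairs = 5,
                           y_center = 6.7, block_size = 5, block_r = 0.5,
                           lognormal_marginals = FALSE, seed = 1L) {
  stopifnot(n_informative <= n_descriptors, noise_sd > 0,
            n_correlated_pairs >= 0, block_r >= 0, block_r < 1)
  if (n_descriptors - n_correlated_pairs < n_informative)
    stop("infeasible: not enough base columns for the informative set",
         call. = FALSE)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 n_informative = as.integer(n_informative),
                 beta = beta, noise_sd = noise_sd,
                 n_correlated_pairs = as.integer(n_correlated_pairs),
                 y_center = y_center,
                 block_size = as.integer(block_size), block_r = block_r,
                 lognormal_marginals = lognormal_marginals,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# The published reference coefficients, reused as default signal magnitudes.
.published_beta <- function() published_kras_model()$coefficients

# Descriptor names in the field's naming families (surface-partition,
# gravitational index, radial-distribution / 3D-MoRSE shells).
.descriptor_names <- function(p, informative_names = NULL) {
  base <- c("TASA", "grav", "PNSA3", "WNSA1", "FPSA1",
            paste0("RDF", rep(c("E", "M", "P", "V", "U"), each = 24),
                   rep(1:24, times = 5)),
            paste0("MoRSE", rep(c("E", "M"), each = 24),
                   rep(1:24, times = 2)))
  nm <- unique(c(informative_names, base))
  if (length(nm) < p) nm <- c(nm, paste0("DESC", seq_len(p - length(nm))))
  nm[seq_len(p)]
}

#' Generate a synthetic QSAR dataset
#'
#' Draws a raw descriptor matrix (informative columns independent,
#' non-informative columns in correlated blocks, all on heterogeneous
#' raw scales), injects near-duplicate columns with |r| > 0.95, and builds
#' the activity as \code{y = y_center + X_std beta + noise} where
#' \code{X_std} is the sample-standardized informative submatrix. The
#' ground truth (support, coefficients, noise SD) is recorded so recovery
#' can be scored. Bit-reproducible from the seed.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a list of class \code{synthetic_dataset}: \code{X} (raw matrix,
#'   named rows/columns), \code{y} (named pIC50 vector), \code{true_beta}
#'   (named), \code{true_support} (names), \code{noise_sd}, \code{seed},
#'   \code{spec}, \code{duplicate_of} (named map for injected duplicates),
#'   \code{raw_means}, \code{raw_sds}.
#' @export
generate <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  p_base <- spec$n_descriptors - spec$n_correlated_pairs
  k <- spec$n_informative

  beta <- spec$beta
  if (identical(beta, "published")) {
    pb <- .published_beta()
    beta <- rep_len(unname(pb), k)
    names(beta) <- NULL
  }
  stopifnot(length(beta) == k)

  info_names <- if (identical(spec$beta, "published") && k == 8)
    names(.published_beta()) else NULL
  nms <- .descriptor_names(p_base, info_names)

  # latent standardized scores: informative independent, rest in blocks
  Z <- matrix(stats::rnorm(n * p_base), n, p_base)
  n_noise <- p_base - k
  if (n_noise > 0 && spec$block_r > 0) {
    blocks <- rep(seq_len(ceiling(n_noise / spec$block_size)),
                  each = spec$block_size, length.out = n_noise)
    for (b in unique(blocks)) {
      cols <- k + which(blocks == b)
      shared <- stats::rnorm(n)
      Z[, cols] <- sqrt(spec$block_r) * shared +
        sqrt(1 - spec$block_r) * Z[, cols]
    }
  }
  if (spec$lognormal_marginals) Z <- exp(Z / 2)

  raw_means <- stats::runif(p_base, -5, 40)
  raw_sds <- exp(stats::runif(p_base, log(0.5), log(20)))
  X <- sweep(sweep(Z, 2, raw_sds, "*"), 2, raw_means, "+")
  colnames(X) <- nms

  dup_of <- character(0)
  if (spec$n_correlated_pairs > 0) {
    src_pool <- if (n_noise >= spec$n_correlated_pairs)
      k + seq_len(n_noise) else seq_len(p_base)
    src <- sample(src_pool, spec$n_correlated_pairs)
    dup_cols <- vapply(src, function(j) {
      # corr(x, x + e) > 0.95 when sd(e) < sd(x)/3; use sd/5 for margin
      X[, j] + stats::rnorm(n, 0, raw_sds[j] / 5)
    }, numeric(n))
    dup_names <- paste0(nms[src], "r")
    colnames(dup_cols) <- dup_names
    dup_of <- stats::setNames(nms[src], dup_names)
    X <- cbind(X, dup_cols)
  }
  rownames(X) <- sprintf("CPD%03d", seq_len(n))

  X_info_std <- scale(X[, seq_len(k), drop = FALSE])
  y <- spec$y_center + drop(X_info_std %*% beta) +
    stats::rnorm(n, 0, spec$noise_sd)
  names(y) <- rownames(X)

  structure(list(X = X, y = y,
                 true_beta = stats::setNames(beta, nms[seq_len(k)]),
                 true_support = nms[seq_len(k)],
                 noise_sd = spec$noise_sd,
                 seed = spec$seed,
                 spec = spec,
                 duplicate_of = dup_of,
                 raw_means = stats::setNames(raw_means, nms),
                 raw_sds = stats::setNames(raw_sds, nms)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic QSAR dataset:", nrow(x$X), "compounds x", ncol(x$X),
      "descriptors;", length(x$true_support), "informative; seed",
      x$seed, "\n")
  invisible(x)
}

#' Generate a screening query set with known domain membership
#'
#' Draws \code{n_inside} query compounds from the same raw descriptor
#' distribution as the training data and \code{n_outside} compounds shifted
#' by \code{outside_shift_sd} standard deviations along a random direction
#' of the standardized descriptor space, then records the ground-truth
#' labels so applicability-domain flagging can be scored.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param n_inside,n_outside query counts.
#' @param outside_shift_sd shift magnitude in standardized units
#'   (default 8).
#' @param seed integer seed.
#' @return a list: \code{X} (raw query matrix), \code{truly_outside}
#'   (logical, aligned with rows).
#' @export
generate_query_set <- function(dataset, n_inside, n_outside,
                               outside_shift_sd = 8, seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  p <- ncol(dataset$X)
  n_q <- n_inside + n_outside
  if (n_q == 0)
    return(list(X = dataset$X[0, , drop = FALSE], truly_outside = logical(0)))
  spec <- dataset$spec
  set.seed(seed)
  k <- spec$n_informative
  p_base <- spec$n_descriptors - spec$n_correlated_pairs
  Z <- matrix(stats::rnorm(n_q * p_base), n_q, p_base)
  n_noise <- p_base - k
  if (n_noise > 0 && spec$block_r > 0) {
    blocks <- rep(seq_len(ceiling(n_noise / spec$block_size)),
                  each = spec$block_size, length.out = n_noise)
    for (b in unique(blocks)) {
      cols <- k + which(blocks == b)
      shared <- stats::rnorm(n_q)
      Z[, cols] <- sqrt(spec$block_r) * shared +
        sqrt(1 - spec$block_r) * Z[, cols]
    }
  }
  if (spec$lognormal_marginals) Z <- exp(Z / 2)
  outside <- rep(c(FALSE, TRUE), c(n_inside, n_outside))
  if (any(outside) && outside_shift_sd > 0) {
    for (i in which(outside)) {
      u <- stats::rnorm(p_base)
      u <- u / sqrt(sum(u^2))
      Z[i, ] <- Z[i, ] + outside_shift_sd * u
    }
  }
  base_names <- names(dataset$raw_means)
  Xq <- sweep(sweep(Z, 2, dataset$raw_sds, "*"), 2, dataset$raw_means, "+")
  colnames(Xq) <- base_names
  if (length(dataset$duplicate_of)) {
    dup <- vapply(names(dataset$duplicate_of), function(dn) {
      src <- dataset$duplicate_of[[dn]]
      Xq[, src] + stats::rnorm(n_q, 0, dataset$raw_sds[[src]] / 5)
    }, numeric(n_q))
    if (n_q == 1L) dup <- matrix(dup, nrow = 1,
                                 dimnames = list(NULL,
                                   names(dataset$duplicate_of)))
    Xq <- cbind(Xq, dup)
  }
  rownames(Xq) <- sprintf("Q%03d", seq_len(n_q))
  list(X = Xq, truly_outside = outside)
}

#' One-call fixture shaped like the KRAS study
#'
#' Convenience generator: 62 compounds, 50 descriptors of which the 8
#' informative ones carry the exact names and coefficient signs of the
#' built-in published equation (TASA, RDFE14, grav, RDFE19, PNSA3, RDFM11,
#' RDFP9, RDFV14), activity centred near pIC50 6.7, plus a 58-compound
#' query set mixing in-domain and far out-of-domain candidates.
#'
#' @param seed integer seed.
#' @param n_query_inside,n_query_outside query-set composition
#'   (defaults 36 and 22).
#' @return a list: \code{dataset} (a \code{synthetic_dataset}),
#'   \code{query} (as \code{\link{generate_query_set}}).
#' @export
study_shaped_fixture <- function(seed = 1L, n_query_inside = 36,
                                 n_query_outside = 22) {
  ds <- generate(synthetic_spec(seed = seed))
  q <- generate_query_set(ds, n_query_inside, n_query_outside,
                          outside_shift_sd = 8, seed = seed + 1000L)
  list(dataset = ds, query = q)
}

#' Write a synthetic dataset to disk as analysis inputs
#'
#' Emits the compound activity table (CSV), the descriptor matrix (CSV), an
#' optional query matrix, and a ground-truth JSON, i.e. exactly the files
#' the ingestion layer reads.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param dir output directory (created if needed).
#' @param query optional query set from \code{\link{generate_query_set}}.
#' @return invisibly, a named list of paths.
#' @export
write_synthetic <- function(dataset, dir, query = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(compounds = file.path(dir, "compounds.csv"),
                descriptors = file.path(dir, "descriptors.csv"),
                truth = file.path(dir, "truth.json"))
  comp <- data.frame(id = rownames(dataset$X),
                     smiles = "",
                     ic50_nM = 10^(9 - dataset$y))
  utils::write.csv(comp, paths$compounds, row.names = FALSE, quote = FALSE)
  write_descriptor_matrix(dataset$X, paths$descriptors)
  if (!is.null(query)) {
    paths$query <- file.path(dir, "query.csv")
    write_descriptor_matrix(query$X, paths$query)
  }
  jsonlite::write_json(
    list(true_support = dataset$true_support,
         true_beta = as.list(dataset$true_beta),
         noise_sd = dataset$noise_sd,
         seed = dataset$seed,
         truly_outside = if (!is.null(query)) query$truly_outside else NULL),
    paths$truth, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(paths)
}
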