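# Shared fixture builders; everything is generated in code at test time.

# Small random regression problem with a known sparse signal.
make_linear_problem <- function(n = 60, p = 8, support = c(1, 3, 5),
                                beta = c(1, 0.8, -0.6), noise_sd = 0.3,
                                seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("c%03d", seq_len(n)),
                              paste0("d", seq_len(p))))
  y <- drop(X[, support, drop = FALSE] %*% beta) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, support = support, beta = beta)
}

# Exhaustive enumeration of every non-empty descriptor mask (the GA oracle).
exhaustive_best_fitness <- function(X, y) {
  p <- ncol(X)
  best <- -Inf
  best_mask <- NULL
  for (code in seq_len(2^p - 1)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
    f <- ga_fitness(mask, X, y)
    if (f > best) { best <- f; best_mask <- mask }
  }
  list(fitness = best, mask = best_mask)
}

# Write a compound CSV on the fly.
write_compound_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Training set of 4 points with sample mean exactly 0 and covariance exactly
# the identity (for closed-form Mahalanobis checks).
euclidean_training_set <- function() {
  a <- sqrt(1.5)
  matrix(c(a, 0, -a, 0, 0, a, 0, -a), ncol = 2, byrow = TRUE,
         dimnames = list(paste0("t", 1:4), c("d1", "d2")))
}
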