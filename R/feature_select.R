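#' Adjusted R-squared
#'
#' \code{1 - (1 - r2) * (n - 1) / (n - k - 1)}: R-squared penalized for the
#' number of predictors k relative to the sample size n.
#'
#' @param r2 unadjusted R-squared.
#' @param n number of observations.
#' @param k number of predictors (excluding the intercept).
#' @return the adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n - k - 1 < 1)
    stop("undefined model: n - k - 1 must be >= 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the study design: 50 generations maximum with early
#' stopping after 10 consecutive generations without improvement of the best
#' fitness. Operator settings (tournament size 2, uniform crossover,
#' per-bit mutation) are conventional for binary-chromosome subset selection.
#'
#' @param population_size number of chromosomes per generation (>= 2).
#' @param max_generations generation budget.
#' @param patience generations without best-fitness improvement before
#'   stopping.
#' @param crossover_rate probability a mating pair undergoes uniform
#'   crossover.
#' @param mutation_rate per-bit flip probability; \code{NULL} means 1/p,
#'   resolved at run time.
#' @param tournament_size selection tournament size.
#' @param elitism number of best chromosomes copied unchanged.
#' @param seed integer seed.
#' @return a list of class \code{ga_config}.
#' @export
ga_config <- function(population_size = 50, max_generations = 50,
                      patience = 10, crossover_rate = 0.9,
                      mutation_rate = NULL, tournament_size = 2,
                      elitism = 1, seed = 1L) {
  stopifnot(max_generations >= 1, patience >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1))
  if (population_size < 2)
    stop("population_size must be at least 2", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 patience = as.integer(patience),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# OLS R^2 of y on the selected columns; NA if the fit is singular.
.ols_r2 <- function(X, y, mask) {
  Xs <- X[, mask, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, Xs), y)
  if (fit$rank < ncol(Xs) + 1L) return(NA_real_)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  1 - rss / tss
}

#' GA fitness: complexity-penalized adjusted R-squared
#'
#' The fitness of a descriptor subset is the adjusted R-squared of the OLS
#' fit on the training set minus k/n, where k is the number of selected
#' descriptors and n the number of training samples. Degenerate masks (empty
#' selection, singular fit, or k too large for the adjustment) score
#' \code{-Inf}.
#'
#' @param mask logical vector over candidate descriptors.
#' @param X_train standardized training descriptor matrix.
#' @param y_train training response.
#' @return the fitness value (scalar).
#' @export
ga_fitness <- function(mask, X_train, y_train) {
  mask <- as.logical(mask)
  k <- sum(mask)
  n <- length(y_train)
  if (k == 0L || n - k - 1 < 1) return(-Inf)
  r2 <- .ols_r2(X_train, y_train, mask)
  if (!is.finite(r2)) return(-Inf)
  adjusted_r2(r2, n, k) - k / n
}

#' Descriptor-subset selection by binary genetic algorithm
#'
#' Elitist generational GA over binary chromosomes (one bit per candidate
#' descriptor) maximizing \code{\link{ga_fitness}}. Selection is by
#' tournament, recombination by uniform crossover, variation by per-bit
#' mutation; the best chromosome is always carried over, so the best-fitness
#' trace is non-decreasing. Stops at \code{max_generations} or after
#' \code{patience} generations without improvement.
#'
#' @param X_train standardized training descriptor matrix.
#' @param y_train training response.
#' @param config a \code{\link{ga_config}}.
#' @return a list of class \code{selection_result}: \code{mask} (named
#'   logical), \code{fitness}, \code{history} (best fitness per generation),
#'   \code{method = "GA"}.
#' @export
ga_select <- function(X_train, y_train, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  X_train <- as.matrix(X_train)
  p <- ncol(X_train)
  pop_n <- config$population_size
  pm <- if (is.null(config$mutation_rate)) 1 / p else config$mutation_rate
  set.seed(config$seed)

  # fitness memoization: converged populations re-evaluate few masks
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fit_of <- function(mask) {
    key <- rawToChar(as.raw(mask + 48L))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- ga_fitness(mask, X_train, y_train)
    cache[[key]] <- val
    val
  }

  pop <- matrix(stats::runif(pop_n * p) < 0.5, nrow = pop_n)
  # guarantee at least one usable chromosome at start
  if (all(rowSums(pop) == 0L)) pop[1, sample.int(p, 1)] <- TRUE
  fitness <- apply(pop, 1, fit_of)
  best_i <- which.max(fitness)
  best_mask <- pop[best_i, ]
  best_fit <- fitness[best_i]
  history <- numeric(0)
  stall <- 0L

  for (gen in seq_len(config$max_generations)) {
    new_pop <- matrix(FALSE, nrow = pop_n, ncol = p)
    ord <- order(fitness, decreasing = TRUE)
    n_elite <- min(config$elitism, pop_n)
    if (n_elite > 0)
      new_pop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    tournament <- function() {
      contenders <- sample.int(pop_n, config$tournament_size, replace = TRUE)
      contenders[which.max(fitness[contenders])]
    }
    i <- n_elite + 1L
    while (i <= pop_n) {
      p1 <- pop[tournament(), ]
      p2 <- pop[tournament(), ]
      if (stats::runif(1) < config$crossover_rate) {
        take1 <- stats::runif(p) < 0.5
        c1 <- ifelse(take1, p1, p2)
        c2 <- ifelse(take1, p2, p1)
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (i > pop_n) break
        flip <- stats::runif(p) < pm
        child <- xor(child, flip)
        new_pop[i, ] <- child
        i <- i + 1L
      }
    }
    pop <- new_pop
    fitness <- apply(pop, 1, fit_of)
    gen_best <- max(fitness)
    if (gen_best > best_fit + 1e-12) {
      best_fit <- gen_best
      best_mask <- pop[which.max(fitness), ]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    history <- c(history, best_fit)
    if (stall >= config$patience) break
  }

  structure(list(mask = stats::setNames(as.logical(best_mask),
                                        colnames(X_train)),
                 fitness = best_fit,
                 history = history,
                 method = "GA",
                 seed = config$seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Descriptor selection (", x$method, "): ", sum(x$mask), " of ",
      length(x$mask), " descriptors, criterion = ",
      format(x$fitness, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Variance-inflation-factor screen
#'
#' Iteratively removes the descriptor with the largest variance inflation
#' factor, VIF_j = 1 / (1 - R2_j) where R2_j is from regressing column j on
#' the remaining columns, until every VIF is at most \code{vif_max}. Exact
#' collinearity yields an infinite VIF and is removed first.
#'
#' @param X numeric descriptor matrix with at least 2 columns (a single
#'   column passes through unchanged).
#' @param vif_max VIF threshold (default 10, the conventional cutoff).
#' @return a \code{selection_result} with \code{method = "VIF"}; the
#'   criterion slot holds the largest remaining VIF.
#' @export
vif_filter <- function(X, vif_max = 10) {
  X <- as.matrix(X)
  all_names <- colnames(X)
  keep <- rep(TRUE, ncol(X))
  vif_one <- function(Xk, j) {
    r2 <- .ols_r2(Xk[, -j, drop = FALSE], Xk[, j], rep(TRUE, ncol(Xk) - 1L))
    if (!is.finite(r2)) r2 <- 1  # singular: the column is fully explained
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    Xk <- X[, keep, drop = FALSE]
    if (ncol(Xk) < 2L) { max_vif <- 1; break }
    vifs <- vapply(seq_len(ncol(Xk)), function(j) vif_one(Xk, j), numeric(1))
    max_vif <- max(vifs)
    if (max_vif <= vif_max) break
    drop_name <- colnames(Xk)[which.max(vifs)]
    keep[match(drop_name, all_names)] <- FALSE
  }
  structure(list(mask = stats::setNames(keep, all_names),
                 fitness = max_vif,
                 history = numeric(0),
                 method = "VIF"),
            class = "selection_result")
}

# Gaussian concentrated-likelihood information criteria (additive constants
# dropped; only differences are ever compared).
.ic <- function(rss, n, k, penalty) n * log(rss / n) + penalty * (k + 1)

# Greedy bidirectional search over single add/drop moves minimizing an
# information criterion with the given per-parameter penalty.
.stepwise_ic <- function(X, y, penalty, start_mask = NULL,
                         pool = seq_len(ncol(X))) {
  X <- as.matrix(X)
  n <- length(y)
  mask <- if (is.null(start_mask)) rep(FALSE, ncol(X)) else start_mask
  ic_of <- function(m) {
    k <- sum(m)
    if (n - k - 1 < 1) return(Inf)
    fit <- stats::lm.fit(cbind(1, X[, m, drop = FALSE]), y)
    if (fit$rank < k + 1L) return(Inf)
    .ic(sum(fit$residuals^2), n, k, penalty)
  }
  cur <- ic_of(mask)
  repeat {
    moves <- list()
    for (j in pool) {
      cand <- mask
      cand[j] <- !cand[j]
      moves[[length(moves) + 1L]] <- list(mask = cand, ic = ic_of(cand))
    }
    ics <- vapply(moves, `[[`, numeric(1), "ic")
    if (min(ics) < cur - 1e-10) {
      best <- moves[[which.min(ics)]]
      mask <- best$mask
      cur <- best$ic
    } else break
  }
  list(mask = mask, ic = cur)
}

#' Bidirectional stepwise selection by AIC
#'
#' Starts from the intercept-only model and repeatedly applies the single
#' descriptor addition or removal that most lowers the Akaike Information
#' Criterion (Gaussian form, \code{n log(RSS/n) + 2 (k+1)}), stopping when no
#' move improves it. The final AIC can never exceed that of the null model.
#'
#' @param X_train standardized training descriptor matrix.
#' @param y_train training response.
#' @return a \code{selection_result} with \code{method = "stepwise"}; the
#'   criterion slot holds the final AIC.
#' @export
stepwise_aic <- function(X_train, y_train) {
  res <- .stepwise_ic(as.matrix(X_train), y_train, penalty = 2)
  structure(list(mask = stats::setNames(res$mask, colnames(X_train)),
                 fitness = res$ic,
                 history = numeric(0),
                 method = "stepwise"),
            class = "selection_result")
}

#' BIC-penalized refit within a descriptor pool
#'
#' Greedy bidirectional search minimizing the Bayesian Information Criterion
#' (\code{n log(RSS/n) + log(n) (k+1)}) restricted to a pool of candidate
#' descriptors from a prior selection (e.g. the GA + VIF survivors). The
#' heavier log(n) penalty typically yields a more parsimonious model than
#' AIC on the same pool.
#'
#' @param X_train standardized training descriptor matrix.
#' @param y_train training response.
#' @param pool_mask logical vector marking the candidate pool.
#' @return a \code{selection_result} with \code{method = "BIC"}.
#' @export
bic_refit <- function(X_train, y_train, pool_mask) {
  pool_mask <- as.logical(pool_mask)
  if (!any(pool_mask)) stop("pool_mask selects no descriptors", call. = FALSE)
  n <- length(y_train)
  res <- .stepwise_ic(as.matrix(X_train), y_train, penalty = log(n),
                      pool = which(pool_mask))
  structure(list(mask = stats::setNames(res$mask, colnames(X_train)),
                 fitness = res$ic,
                 history = numeric(0),
                 method = "BIC"),
            class = "selection_result")
}

#' Serialize a selection result to JSON
#'
#' @param sel a \code{selection_result}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(method = sel$method,
         selected = names(sel$mask)[sel$mask],
         criterion = sel$fitness,
         history = sel$history),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
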