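#' Virtual screening of candidate compounds
#'
#' Runs the full scoring chain on a raw query descriptor matrix: project
#' into the model space with the training scaling statistics, predict
#' pIC50, attach split-conformal intervals when a calibrated model is
#' supplied, flag applicability-domain membership by Mahalanobis distance
#' against the standardized training data, and call hits with a strict
#' \code{pIC50 > hit_threshold} rule. Outside-domain compounds keep their
#' predictions but are labelled extrapolations; triage should prefer the
#' inside-domain hits.
#'
#' @param model a \code{qsar_lm}.
#' @param scaling \code{\link{scaling_params}} estimated on the training
#'   set (may be \code{NULL} if \code{X_query_raw} is already standardized).
#' @param X_query_raw raw query descriptor matrix covering the model's
#'   descriptors.
#' @param X_train_std standardized training matrix restricted to the model
#'   descriptors, used for the domain assessment.
#' @param conformal optional \code{conformal_model} for intervals.
#' @param ad_mode \code{"chi2"} (analytic chi-squared threshold) or
#'   \code{"fixed"} (hard cutoff).
#' @param ad_cutoff the fixed cutoff used when \code{ad_mode = "fixed"}
#'   (default 15).
#' @param hit_threshold predicted-pIC50 hit rule (default 8.0, strict
#'   inequality).
#' @return an object of class \code{screening_result}: per-compound data
#'   frame \code{table} (\code{id}, \code{pic50_pred}, \code{interval_low},
#'   \code{interval_high}, \code{mahalanobis_d2}, \code{inside_doa},
#'   \code{is_hit}) and globals \code{hit_threshold}, \code{md_threshold},
#'   \code{n_inside}, \code{n_outside}.
#' @export
screen <- function(model, scaling, X_query_raw, X_train_std,
                   conformal = NULL, ad_mode = c("chi2", "fixed"),
                   ad_cutoff = 15, hit_threshold = 8.0) {
  ad_mode <- match.arg(ad_mode)
  stopifnot(inherits(model, "qsar_lm"))
  Xq_raw <- as.matrix(X_query_raw)
  need <- names(model$coefficients)
  miss <- setdiff(need, colnames(Xq_raw))
  if (length(miss))
    stop("query matrix is missing model descriptor(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  Xq <- if (!is.null(scaling)) apply_scaling(Xq_raw, scaling) else Xq_raw
  Xq <- Xq[, need, drop = FALSE]
  Xt <- as.matrix(X_train_std)[, need, drop = FALSE]

  pred <- predict(model, Xq)
  if (!is.null(conformal)) {
    lo <- pred - conformal$q_hat
    hi <- pred + conformal$q_hat
  } else lo <- hi <- rep(NA_real_, length(pred))

  ad <- mahalanobis_doa(
    Xt, Xq,
    threshold_override = if (ad_mode == "fixed") ad_cutoff else NULL)

  tab <- data.frame(id = rownames(Xq) %||% seq_len(nrow(Xq)),
                    pic50_pred = unname(pred),
                    interval_low = lo, interval_high = hi,
                    mahalanobis_d2 = ad$table$mahalanobis_d2,
                    inside_doa = ad$table$inside_md,
                    is_hit = unname(pred) > hit_threshold)
  structure(list(table = tab,
                 hit_threshold = hit_threshold,
                 md_threshold = ad$md_threshold,
                 ad_mode = ad_mode,
                 n_inside = sum(tab$inside_doa),
                 n_outside = sum(!tab$inside_doa)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Screened", nrow(x$table), "compound(s):",
      sum(x$table$is_hit), "hit(s) at pIC50 >", x$hit_threshold, "|",
      x$n_inside, "inside /", x$n_outside, "outside the domain\n")
  invisible(x)
}

#' Summarize screening hits
#'
#' Hits sorted by predicted pIC50 (descending, ties by id), counts of hits
#' inside versus outside the applicability domain, and the reliable-hit
#' subset: hits that are also inside the domain, the compounds worth
#' prioritizing experimentally.
#'
#' @param result a \code{screening_result}.
#' @return a list: \code{hits} (sorted data frame), \code{n_hits},
#'   \code{n_hits_inside}, \code{n_hits_outside}, \code{reliable_hits}.
#' @export
summarize_hits <- function(result) {
  stopifnot(inherits(result, "screening_result"))
  hits <- result$table[result$table$is_hit, , drop = FALSE]
  hits <- hits[order(-hits$pic50_pred, hits$id), , drop = FALSE]
  rownames(hits) <- NULL
  reliable <- hits[hits$inside_doa, , drop = FALSE]
  list(hits = hits,
       n_hits = nrow(hits),
       n_hits_inside = nrow(reliable),
       n_hits_outside = nrow(hits) - nrow(reliable),
       reliable_hits = reliable)
}

#' Write a screening report (TSV per compound + JSON summary)
#'
#' @param result a \code{screening_result}.
#' @param tsv_path per-compound table output.
#' @param json_path summary output (optional).
#' @return invisibly, \code{tsv_path}.
#' @export
write_screening_report <- function(result, tsv_path, json_path = NULL) {
  utils::write.table(result$table, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(json_path)) {
    s <- summarize_hits(result)
    jsonlite::write_json(
      list(hit_threshold = result$hit_threshold,
           md_threshold = result$md_threshold,
           ad_mode = result$ad_mode,
           n_screened = nrow(result$table),
           n_inside = result$n_inside,
           n_outside = result$n_outside,
           n_hits = s$n_hits,
           n_hits_inside = s$n_hits_inside,
           reliable_hit_ids = s$reliable_hits$id),
      json_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(tsv_path)
}
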