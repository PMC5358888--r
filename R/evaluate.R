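# Model evaluation: SMAPE scoring, global summaries, and
# training-vs-testing divergence screening.

#' Symmetric mean absolute percentage error
#'
#' `smape(y, yhat) = (1/n) sum_t |y_t - yhat_t| / (y_t + yhat_t)`, the
#' unhalved form bounded in `[0, 1]` for non-negative profiles (0.13 reads
#' as a 13% error).  A term with `y_t = yhat_t = 0` contributes 0 via the
#' `epsilon` guard on the denominator.
#'
#' @param measured numeric vector of non-negative measured values.
#' @param predicted numeric vector of non-negative predictions, same length.
#' @param epsilon small positive denominator floor (default 1e-12).
#' @return a scalar in `[0, 1]`.
#' @export
smape <- function(measured, predicted, epsilon = 1e-12) {
  if (length(measured) != length(predicted) || length(measured) < 1)
    rbf_stop("measured and predicted must have equal length >= 1",
             "alignment_error")
  if (any(measured < 0) || any(predicted < 0))
    rbf_stop("SMAPE is defined for non-negative values", "domain_error")
  mean(abs(measured - predicted) / pmax(measured + predicted, epsilon))
}

#' Summarize prediction errors across metabolites
#'
#' The per-metabolite statistic is the mean SMAPE of the consensus
#' prediction over the test replicates; the global summary is the median of
#' those per-metabolite means and their standard deviation.
#'
#' @param results list of `prediction_result` objects (one per metabolite).
#' @return list of class `evaluation_summary`: `per_metabolite` (data.frame
#'   `metabolite_id, mean_smape, sd_smape, n_replicates`), `global_median`,
#'   `global_sd`, and the retained per-replicate `smape_distribution`.
#' @export
summarize_predictions <- function(results) {
  stopifnot(length(results) >= 1)
  per <- do.call(rbind, lapply(results, function(pr) {
    s <- vapply(pr$replicates, `[[`, numeric(1), "smape")
    data.frame(metabolite_id = pr$target_id,
               mean_smape = mean(s), sd_smape = stats::sd(s),
               n_replicates = length(s), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  dist <- lapply(results, function(pr)
    vapply(pr$replicates, `[[`, numeric(1), "smape"))
  names(dist) <- per$metabolite_id
  structure(list(per_metabolite = per,
                 global_median = stats::median(per$mean_smape),
                 global_sd = stats::sd(per$mean_smape),
                 smape_distribution = dist),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("evaluation_summary: %d metabolites, median SMAPE %.4f +/- %.4f (sd)\n",
              nrow(x$per_metabolite), x$global_median, x$global_sd))
  invisible(x)
}

# Welch t-test p-value that tolerates (near-)constant samples: identical
# constant samples are indistinguishable (p = 1), distinct constants are
# trivially different (p = 0)
welch_p <- function(a, b) {
  if (stats::sd(a) < .Machine$double.eps^0.5 * max(1, abs(mean(a))) &&
      stats::sd(b) < .Machine$double.eps^0.5 * max(1, abs(mean(b))))
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Screen for divergence between training and testing replicates
#'
#' Welch two-sample t-test per (metabolite, time point), Benjamini-Hochberg
#' adjustment over all tests jointly, and the symmetric percent difference
#' of group means.  A cell is flagged when the adjusted p-value is below
#' `alpha` *and* the percent difference exceeds `mean_diff_threshold`.
#'
#' @param ds a `metab_dataset`.
#' @param split a `split_assignment`.
#' @param alpha FDR level (default 0.05).
#' @param mean_diff_threshold fractional mean-difference cutoff (default
#'   0.20, i.e. 20%).
#' @return list of class `divergence_report`: `table` (data.frame
#'   `metabolite_id, time_days, pct_diff, p_raw, p_adj, flagged`) and
#'   `flagged_fraction`.
#' @export
compare_train_test <- function(ds, split, alpha = 0.05,
                               mean_diff_threshold = 0.20) {
  tr <- split$training_replicates
  te <- split$testing_replicates
  if (length(tr) < 2 || length(te) < 2)
    rbf_stop("need >= 2 replicates on each side", "insufficient_data_error")
  mets <- ds$metabolites$metabolite_id
  grid <- expand.grid(m = seq_along(mets), t = seq_along(ds$time_days))
  res <- mapply(function(m, t) {
    a <- ds$conc[mets[m], tr, ][, t]
    b <- ds$conc[mets[m], te, ][, t]
    ma <- mean(a); mb <- mean(b)
    denom <- (ma + mb) / 2
    pct <- if (denom > 0) abs(ma - mb) / denom else 0
    c(pct, welch_p(a, b))
  }, grid$m, grid$t)
  tab <- data.frame(metabolite_id = mets[grid$m],
                    time_days = ds$time_days[grid$t],
                    pct_diff = res[1, ], p_raw = res[2, ],
                    stringsAsFactors = FALSE)
  tab$p_adj <- stats::p.adjust(tab$p_raw, method = "BH")
  tab$flagged <- tab$p_adj < alpha & tab$pct_diff > mean_diff_threshold
  structure(list(table = tab, flagged_fraction = mean(tab$flagged),
                 alpha = alpha, mean_diff_threshold = mean_diff_threshold),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat(sprintf(
    "divergence_report: %.1f%% of (metabolite, time) cells flagged (FDR %.2g, >%.0f%% mean difference)\n",
    100 * x$flagged_fraction, x$alpha, 100 * x$mean_diff_threshold))
  invisible(x)
}
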