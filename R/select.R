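# Quantitative biomarker-panel selection: exhaustive enumeration of
# candidate subsets, scored by leave-one-replicate-out cross-validation of
# the full ensemble workflow within the training replicates.

#' Enumerate all k-subsets of a candidate list
#'
#' @param candidates character vector of candidate ids (sorted internally so
#'   the enumeration is deterministic and lexicographic).
#' @param k subset size, `1 <= k <= length(candidates)`.
#' @return list of character vectors, `choose(n, k)` subsets, no duplicates.
#' @export
enumerate_subsets <- function(candidates, k) {
  n <- length(candidates)
  if (k < 1 || k > n)
    rbf_stop(sprintf("k must be in [1, %d]", n), "usage_error")
  cand <- sort(unique(as.character(candidates)))
  if (length(cand) != n) rbf_stop("duplicate candidate ids", "usage_error")
  utils::combn(cand, k, simplify = FALSE)
}

# Leave-one-replicate-out CV of the ensemble workflow: for each fold, train
# one member per held-in replicate with `input_ids` as model inputs, predict
# the held-out replicate's target profiles from its biomarkers alone, score
# the consensus by SMAPE.  Returns the mean over folds and targets plus the
# per-fold means.
loro_cv_smape <- function(ds, training_replicates, input_ids, spec, target_pool) {
  stopifnot(length(training_replicates) >= 2, length(target_pool) >= 1)
  fold_means <- vapply(seq_along(training_replicates), function(i) {
    held_out <- training_replicates[i]
    held_in <- training_replicates[-i]
    fold_split <- list(training_replicates = held_in)
    u_out <- biomarker_matrix(ds, held_out, input_ids)
    scores <- vapply(target_pool, function(tgt) {
      em <- tryCatch(
        train_ensemble(ds, fold_split, tgt, spec, biomarker_ids = input_ids),
        error = function(e) stop(sprintf("CV fold %d (held-out %s), target %s: %s",
                                         i, held_out, tgt, conditionMessage(e)),
                                 call. = FALSE))
      pr <- predict_consensus(em, list(u_out),
                              measured = list(ds$conc[tgt, held_out, ]))
      pr$summary_smape
    }, numeric(1))
    mean(scores)
  }, numeric(1))
  list(mean_smape = mean(fold_means), per_fold = fold_means)
}

#' Cross-validate one biomarker subset
#'
#' Scores `subset` as a predictor panel by leave-one-replicate-out
#' cross-validation over the training replicates (10 replicates give the
#' 10-fold scheme): in each fold an ensemble is trained on the held-in
#' replicates and the held-out replicate's targets are predicted from its
#' subset profiles alone.  Candidate biomarkers outside the subset are
#' candidate inputs, not evaluation targets, so the target pool excludes
#' all of `candidates`.
#'
#' @param ds a `metab_dataset`.
#' @param training_replicates replicate ids to cross-validate within (>= 2).
#' @param subset biomarker ids to evaluate as inputs.
#' @param spec an [oe_spec()] sized to `length(subset)` inputs.
#' @param candidates the full candidate pool (default `subset`), excluded
#'   from the scored targets.
#' @return list of class `subset_cv_result`: `subset`, `mean_smape`,
#'   `per_fold`.
#' @export
cross_validate_subset <- function(ds, training_replicates, subset,
                                  spec = oe_spec(length(subset)),
                                  candidates = subset) {
  if (!all(subset %in% ds$metabolites$metabolite_id))
    rbf_stop("subset contains unmeasured metabolites", "reference_error")
  target_pool <- setdiff(ds$metabolites$metabolite_id, candidates)
  cv <- loro_cv_smape(ds, training_replicates, subset, spec, target_pool)
  structure(list(subset = as.character(subset), mean_smape = cv$mean_smape,
                 per_fold = cv$per_fold),
            class = "subset_cv_result")
}

#' Select a biomarker panel by exhaustive cross-validation
#'
#' Runs [cross_validate_subset()] for every k-subset of the candidates and
#' returns the top-ranked subset together with the full score table and the
#' set of subsets scoring within `tolerance` (absolute, on the SMAPE `[0,1]`
#' scale) of the best.  Ties rank lexicographically.
#'
#' @param ds a `metab_dataset`.
#' @param training_replicates replicate ids for the CV.
#' @param candidates candidate biomarker ids (e.g. 8 metabolites).
#' @param k panel size (e.g. 5, giving 56 subsets of 8 candidates).
#' @param spec an [oe_spec()] sized to k inputs.
#' @param tolerance near-tie band around the best mean SMAPE (default 0.01,
#'   i.e. within one SMAPE percentage point).
#' @return list of class `biomarker_selection`: `chosen` (character vector),
#'   `table` (data.frame `subset, mean_smape, rank, within_tolerance`),
#'   `tolerance`.
#' @export
select_biomarkers <- function(ds, training_replicates, candidates, k,
                              spec = oe_spec(k), tolerance = 0.01) {
  subsets <- enumerate_subsets(candidates, k)
  scores <- vapply(subsets, function(s)
    cross_validate_subset(ds, training_replicates, s, spec,
                          candidates = candidates)$mean_smape,
    numeric(1))
  keys <- vapply(subsets, paste, character(1), collapse = ";")
  ord <- order(scores, keys)
  rank <- integer(length(scores)); rank[ord] <- seq_along(scores)
  within <- scores <= min(scores) + tolerance
  tab <- data.frame(subset = keys, mean_smape = scores, rank = rank,
                    within_tolerance = within, stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  structure(list(chosen = subsets[[ord[1]]], table = tab,
                 tolerance = tolerance),
            class = "biomarker_selection")
}

#' @export
print.biomarker_selection <- function(x, ...) {
  cat(sprintf("biomarker_selection: chose {%s}, mean CV SMAPE %.4f; %d/%d subsets within %.3g\n",
              paste(x$chosen, collapse = ", "), x$table$mean_smape[1],
              sum(x$table$within_tolerance), nrow(x$table), x$tolerance))
  invisible(x)
}
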