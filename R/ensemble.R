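# Per-replicate ensemble training and median-consensus prediction.
#
# One model is fitted per training replicate (a stored blood bag followed
# longitudinally), so the ensemble carries the biological bag-to-bag
# variation of the training set; the consensus at each time point is the
# median of the member predictions, which is robust to individual unstable
# fits.

#' Train an ensemble of OE models for one target metabolite
#'
#' Fits one model per training replicate, using that replicate's biomarker
#' profiles as inputs and its target profile as output.
#'
#' @param ds a `metab_dataset`.
#' @param split a `split_assignment` from [split_replicates()] (or any list
#'   with a `training_replicates` field).
#' @param target_id a non-biomarker metabolite to model.
#' @param spec an [oe_spec()]; default the static 5-input FIR structure
#'   implied by `biomarker_ids`.
#' @param biomarker_ids ordered input metabolites (default the dataset's
#'   designated biomarkers).
#' @return an object of class `ensemble_model` with one member per training
#'   replicate, in training-replicate order.
#' @export
train_ensemble <- function(ds, split, target_id,
                           spec = oe_spec(length(biomarker_ids)),
                           biomarker_ids = ds$biomarker_ids) {
  if (target_id %in% biomarker_ids)
    rbf_stop(paste(target_id, "is a biomarker input, not a target"), "usage_error")
  if (!target_id %in% ds$metabolites$metabolite_id)
    rbf_stop(paste("unknown metabolite", target_id), "reference_error")
  members <- lapply(split$training_replicates, function(r) {
    tryCatch(
      fit_oe(spec, biomarker_matrix(ds, r, biomarker_ids),
             ds$conc[target_id, r, ], input_ids = biomarker_ids),
      error = function(e) stop(sprintf("fit failed for target %s, replicate %s: %s",
                                       target_id, r, conditionMessage(e)),
                               call. = FALSE))
  })
  names(members) <- split$training_replicates
  structure(list(target_id = target_id, members = members, spec = spec,
                 biomarker_ids = as.character(biomarker_ids)),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model for %s: %d members, inputs %s\n", x$target_id,
              length(x$members), paste(x$biomarker_ids, collapse = ", ")))
  invisible(x)
}

#' Predict consensus concentration profiles from biomarkers alone
#'
#' Runs every ensemble member on each test replicate's biomarker profiles
#' and takes the per-time-point median across members (even member count:
#' mean of the two central values).  Measured target profiles, when
#' supplied, are used only for SMAPE scoring, never for prediction.
#'
#' @param em an `ensemble_model`.
#' @param inputs named list (one entry per test replicate) of biomarker
#'   matrices, time points x inputs in `em$biomarker_ids` order; a single
#'   matrix is treated as one unnamed replicate.
#' @param measured optional named list of measured target profiles (numeric
#'   vectors on the same grid) for scoring.
#' @param epsilon SMAPE denominator guard, see [smape()].
#' @return an object of class `prediction_result`: per replicate the member
#'   prediction matrix (members x times), `consensus`, `measured`, `smape`;
#'   plus `summary_smape`, the mean SMAPE over scored replicates.
#' @export
predict_consensus <- function(em, inputs, measured = NULL, epsilon = 1e-12) {
  if (is.matrix(inputs)) inputs <- list(inputs)
  per_rep <- lapply(seq_along(inputs), function(k) {
    u <- inputs[[k]]
    preds <- t(vapply(em$members, function(m) simulate_oe(m, u),
                      numeric(nrow(u))))
    consensus <- apply(preds, 2, stats::median)
    meas <- if (!is.null(measured)) measured[[k]] else NULL
    sm <- NA_real_
    if (!is.null(meas)) {
      if (length(meas) != ncol(preds))
        rbf_stop("measured profile length does not match the prediction grid",
                 "alignment_error")
      sm <- smape(meas, pmax(consensus, 0), epsilon = epsilon)
    }
    list(member_predictions = preds, consensus = consensus,
         measured = meas, smape = sm)
  })
  names(per_rep) <- names(inputs)
  smapes <- vapply(per_rep, `[[`, numeric(1), "smape")
  structure(list(target_id = em$target_id, replicates = per_rep,
                 summary_smape = if (all(is.na(smapes))) NA_real_
                                 else mean(smapes, na.rm = TRUE)),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result for %s: %d replicates, mean SMAPE %s\n",
              x$target_id, length(x$replicates),
              ifelse(is.na(x$summary_smape), "NA",
                     sprintf("%.4f", x$summary_smape))))
  invisible(x)
}

#' Predict test replicates of a dataset with a trained ensemble
#'
#' Convenience wrapper around [predict_consensus()] that extracts each test
#' replicate's biomarker matrix and measured target profile from the
#' dataset.
#'
#' @param em an `ensemble_model`.
#' @param ds a `metab_dataset`.
#' @param replicate_ids the replicates to predict (e.g. the testing half).
#' @return a `prediction_result`.
#' @export
predict_targets <- function(em, ds, replicate_ids) {
  inputs <- lapply(replicate_ids, function(r)
    biomarker_matrix(ds, r, em$biomarker_ids))
  measured <- lapply(replicate_ids, function(r) ds$conc[em$target_id, r, ])
  names(inputs) <- names(measured) <- replicate_ids
  predict_consensus(em, inputs, measured)
}

#' Serialize an ensemble to a directory of model files
#' @param em an `ensemble_model`.
#' @param dir directory (created if needed); one file per member plus the
#'   member order.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(em, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(names(em$members), file.path(dir, "members.txt"))
  for (r in names(em$members))
    write_oe_model(em$members[[r]], file.path(dir, paste0(r, ".oe")))
  invisible(dir)
}

#' Read an ensemble written by [write_ensemble()]
#' @param dir ensemble directory.
#' @param target_id target metabolite id to attach.
#' @return an `ensemble_model`.
#' @export
read_ensemble <- function(dir, target_id) {
  reps <- readLines(file.path(dir, "members.txt"))
  members <- lapply(reps, function(r) read_oe_model(file.path(dir, paste0(r, ".oe"))))
  names(members) <- reps
  structure(list(target_id = target_id, members = members,
                 spec = members[[1]]$spec,
                 biomarker_ids = members[[1]]$input_ids),
            class = "ensemble_model")
}
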