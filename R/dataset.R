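# Data model and I/O for replicate-resolved metabolite time courses.
#
# A `metab_dataset` holds concentrations on a single shared time grid for
# every (metabolite, replicate) pair, together with the designation of which
# metabolites are the biomarker inputs.  Storage is a dense 3-d array
# [metabolite, replicate, time]; completeness (no missing cells) is a hard
# invariant, not an imputation target, because every downstream statistic
# assumes a full grid.

#' Construct a metabolomics time-course dataset
#'
#' @param conc numeric 3-d array `[metabolite, replicate, time]` with
#'   dimnames on the first two margins; all values finite and non-negative.
#' @param compartments character vector, one of `"intracellular"` or
#'   `"extracellular"` per metabolite (in `conc` row order).
#' @param time_days strictly increasing numeric vector of sampling days.
#' @param biomarker_ids character subset of the metabolite ids designated as
#'   model inputs; the remaining metabolites are prediction targets.
#' @return an object of class `metab_dataset`.
#' @export
metab_dataset <- function(conc, compartments, time_days, biomarker_ids) {
  if (!is.array(conc) || length(dim(conc)) != 3)
    rbf_stop("conc must be a 3-d array [metabolite, replicate, time]", "format_error")
  met_ids <- dimnames(conc)[[1]]
  rep_ids <- dimnames(conc)[[2]]
  if (is.null(met_ids) || is.null(rep_ids))
    rbf_stop("conc needs metabolite and replicate dimnames", "format_error")
  if (anyDuplicated(met_ids) || anyDuplicated(rep_ids))
    rbf_stop("duplicate metabolite or replicate identifiers", "format_error")
  if (length(time_days) != dim(conc)[3] || any(diff(time_days) <= 0))
    rbf_stop("time_days must be strictly increasing and match conc", "format_error")
  if (anyNA(conc))
    rbf_stop("missing (metabolite, replicate, time) cells", "completeness_error")
  if (any(conc < 0))
    rbf_stop("negative concentrations", "domain_error")
  if (length(compartments) != length(met_ids) ||
      !all(compartments %in% c("intracellular", "extracellular")))
    rbf_stop("compartments must be intracellular/extracellular per metabolite",
             "format_error")
  if (!all(biomarker_ids %in% met_ids))
    rbf_stop("biomarker id absent from data", "reference_error")
  structure(list(
    conc = conc,
    metabolites = data.frame(metabolite_id = met_ids, compartment = compartments,
                             stringsAsFactors = FALSE),
    replicate_ids = rep_ids,
    time_days = as.numeric(time_days),
    biomarker_ids = as.character(biomarker_ids)
  ), class = "metab_dataset")
}

#' @export
print.metab_dataset <- function(x, ...) {
  cat(sprintf(
    "metab_dataset: %d metabolites (%d biomarkers, %d targets), %d replicates, %d time points (day %g-%g)\n",
    nrow(x$metabolites), length(x$biomarker_ids),
    nrow(x$metabolites) - length(x$biomarker_ids),
    length(x$replicate_ids), length(x$time_days),
    min(x$time_days), max(x$time_days)))
  invisible(x)
}

#' Target (non-biomarker) metabolite ids of a dataset
#' @param ds a `metab_dataset`.
#' @return character vector of metabolite ids that are prediction targets.
#' @export
target_ids <- function(ds) {
  setdiff(ds$metabolites$metabolite_id, ds$biomarker_ids)
}

#' Biomarker input matrix for one replicate
#'
#' @param ds a `metab_dataset`.
#' @param replicate_id one replicate identifier.
#' @param biomarker_ids inputs to extract, default the dataset's designation.
#' @return numeric matrix, time points x biomarkers.
#' @export
biomarker_matrix <- function(ds, replicate_id, biomarker_ids = ds$biomarker_ids) {
  if (!replicate_id %in% ds$replicate_ids)
    rbf_stop(paste("unknown replicate", replicate_id), "reference_error")
  m <- t(ds$conc[biomarker_ids, replicate_id, , drop = FALSE][, 1, ])
  if (length(biomarker_ids) == 1L)  # drop semantics for single input
    m <- matrix(ds$conc[biomarker_ids, replicate_id, ], ncol = 1)
  dimnames(m) <- list(NULL, biomarker_ids)
  m
}

dataset_columns <- c("metabolite_id", "compartment", "replicate_id",
                     "time_days", "concentration")

#' Read a tidy concentration CSV into a dataset
#'
#' The file must contain the columns `metabolite_id, compartment,
#' replicate_id, time_days, concentration` (any row order) and a complete
#' grid: every metabolite measured in every replicate at every time point.
#' Incomplete grids are an error — values are never imputed.
#'
#' @param path CSV file path.
#' @param biomarker_ids metabolite ids to designate as biomarker inputs.
#' @return a [metab_dataset()].
#' @export
read_dataset <- function(path, biomarker_ids) {
  if (!file.exists(path)) rbf_stop(paste("no such file:", path), "format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(dataset_columns %in% names(df)))
    rbf_stop(paste("missing column(s):",
                   paste(setdiff(dataset_columns, names(df)), collapse = ", ")),
             "format_error")
  met_ids <- unique(df$metabolite_id)
  rep_ids <- unique(df$replicate_id)
  times <- sort(unique(df$time_days))
  conc <- array(NA_real_, dim = c(length(met_ids), length(rep_ids), length(times)),
                dimnames = list(met_ids, rep_ids, NULL))
  idx <- cbind(match(df$metabolite_id, met_ids),
               match(df$replicate_id, rep_ids),
               match(df$time_days, times))
  if (anyDuplicated(idx))
    rbf_stop("duplicate (metabolite, replicate, time) rows", "format_error")
  conc[idx] <- df$concentration
  if (anyNA(conc))
    rbf_stop("incomplete grid: some (metabolite, replicate, time) cells missing",
             "completeness_error")
  comp <- df$compartment[match(met_ids, df$metabolite_id)]
  metab_dataset(conc, comp, times, biomarker_ids)
}

#' Write a dataset as a tidy concentration CSV
#'
#' Times and concentrations are written with 17 significant digits so that
#' `read_dataset(write_dataset(ds))` round-trips doubles exactly.
#'
#' @param ds a `metab_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  met <- ds$metabolites$metabolite_id
  grid <- expand.grid(t = seq_along(ds$time_days),
                      r = seq_along(ds$replicate_ids),
                      m = seq_along(met))
  df <- data.frame(
    metabolite_id = met[grid$m],
    compartment = ds$metabolites$compartment[grid$m],
    replicate_id = ds$replicate_ids[grid$r],
    time_days = fmt_num(ds$time_days[grid$t]),
    concentration = fmt_num(ds$conc[cbind(grid$m, grid$r, grid$t)]),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop sampling days from a dataset
#'
#' Quality-control exclusion of whole time points (e.g. an anomalous late
#' sampling day); every excluded day must match a grid value exactly.
#'
#' @param ds a `metab_dataset`.
#' @param excluded_days numeric days to remove (may be empty).
#' @return the dataset restricted to the remaining time points.
#' @export
exclude_timepoints <- function(ds, excluded_days) {
  if (length(excluded_days) == 0) return(ds)
  pos <- match(excluded_days, ds$time_days)
  if (anyNA(pos))
    rbf_stop(paste("excluded day(s) not on the sampling grid:",
                   paste(excluded_days[is.na(pos)], collapse = ", ")),
             "reference_error")
  keep <- setdiff(seq_along(ds$time_days), pos)
  metab_dataset(ds$conc[, , keep, drop = FALSE], ds$metabolites$compartment,
                ds$time_days[keep], ds$biomarker_ids)
}

#' Flag time points with anomalous across-replicate dispersion
#'
#' For each extracellular metabolite, computes the across-replicate
#' coefficient of variation (CV) at every time point and flags a time point
#' whose CV exceeds `cv_ratio_threshold` times the median CV of that
#' metabolite over all other time points.  Advisory only: exclusion remains
#' an explicit call to [exclude_timepoints()].
#'
#' @param ds a `metab_dataset` with at least two replicates.
#' @param cv_ratio_threshold positive multiplier on the median CV (default 3).
#' @return data.frame with columns `time_days, metabolite_id, cv, cv_ratio`,
#'   one row per flag (zero rows when nothing is flagged).
#' @export
flag_anomalous_timepoints <- function(ds, cv_ratio_threshold = 3) {
  if (length(ds$replicate_ids) < 2)
    rbf_stop("need at least 2 replicates to assess dispersion",
             "insufficient_data_error")
  stopifnot(cv_ratio_threshold > 0)
  extr <- ds$metabolites$metabolite_id[ds$metabolites$compartment == "extracellular"]
  out <- list()
  for (m in extr) {
    x <- ds$conc[m, , ]                      # replicates x times
    mu <- colMeans(x)
    s <- apply(x, 2, stats::sd)
    cv <- ifelse(mu > 0, s / mu, ifelse(s > 0, Inf, 0))
    for (t in seq_along(ds$time_days)) {
      ref <- stats::median(cv[-t])
      # Inf * 0 is NaN; a NaN comparison is NA and isTRUE() keeps it unflagged
      flagged <- cv[t] > cv_ratio_threshold * ref
      if (isTRUE(flagged)) {
        out[[length(out) + 1L]] <- data.frame(
          time_days = ds$time_days[t], metabolite_id = m, cv = cv[t],
          cv_ratio = if (ref > 0) cv[t] / ref else Inf,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(time_days = numeric(0), metabolite_id = character(0),
                      cv = numeric(0), cv_ratio = numeric(0)))
  do.call(rbind, out)
}

#' Randomly split replicates into training and testing halves
#'
#' Uniform random partition; with an odd replicate count the training side
#' receives the extra replicate.  Uses its own seeded stream so the split
#' never changes when Monte-Carlo seeds elsewhere change.
#'
#' @param ds a `metab_dataset` with at least two replicates.
#' @param seed integer seed.
#' @return a list of class `split_assignment` with `training_replicates`,
#'   `testing_replicates` and `seed`.
#' @export
split_replicates <- function(ds, seed) {
  reps <- ds$replicate_ids
  if (length(reps) < 2)
    rbf_stop("need at least 2 replicates to split", "insufficient_data_error")
  n_train <- ceiling(length(reps) / 2)
  perm <- with_seed(derive_seed(seed, "split"), sample(reps))
  structure(list(
    training_replicates = reps[reps %in% perm[seq_len(n_train)]],
    testing_replicates = reps[reps %in% perm[-seq_len(n_train)]],
    seed = as.integer(seed)
  ), class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment (seed %d): %d training / %d testing replicates\n",
              x$seed, length(x$training_replicates), length(x$testing_replicates)))
  invisible(x)
}
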