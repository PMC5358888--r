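# Synthetic multi-replicate storage metabolomics generator.
#
# Emulates the statistical shape the analysis assumes: a shared sampling
# grid over 45 days of cold storage, extracellular biomarker profiles with
# the characteristic three-phase (piecewise-linear, monotone) decay or
# accumulation, per-replicate ("blood bag") multiplicative variation,
# measurement noise, target metabolites that are true static linear mixes
# of the biomarkers (the model family's own generative truth, so parameter
# recovery is well-posed), a handful of pure-noise targets, and optionally
# an inflated-dispersion artifact at one sampling day mimicking a bad
# extracellular measurement batch.

#' Specify a synthetic dataset
#'
#' Defaults emulate the dimensions of a 20-bag, 14-time-point, 96-metabolite
#' storage study with 5 designated biomarkers (85 signal + 6 noise targets).
#'
#' @param n_replicates number of blood-bag replicates (default 20).
#' @param time_days sampling grid in days (default the 14 nominal days
#'   0,3,7,10,14,17,21,24,28,31,35,38,42,45).
#' @param n_biomarkers number of biomarker inputs (default 5).
#' @param n_signal_targets targets that are true linear responses to the
#'   biomarkers (default 85).
#' @param n_noise_targets targets that are trend-free noise about a
#'   constant, with no biomarker dependence (default 6).
#' @param coeff_range interval the true mixing coefficients are drawn from
#'   (default `c(0.2, 2)`; positive, so noiseless signal targets stay
#'   strictly positive and zero-truncation never engages).
#' @param noise_sd proportional measurement-noise level: each observed value
#'   is the clean value times `1 + Normal(0, noise_sd^2)` (default 0.05,
#'   i.e. 5% multiplicative error, the usual error model for quantified
#'   metabolite concentrations).
#' @param bag_sd standard deviation of the per-replicate lognormal
#'   multiplicative bag effect (default 0.1).
#' @param day31_artifact inflate across-replicate dispersion x10 for
#'   extracellular metabolites at day 31 (default `FALSE`).
#' @param lag_mixing mix one-sample-lagged biomarkers into signal targets
#'   (`nk = 1` truth) instead of contemporaneous ones (default `FALSE`).
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_replicates = 20,
                       time_days = c(0, 3, 7, 10, 14, 17, 21, 24, 28, 31, 35, 38, 42, 45),
                       n_biomarkers = 5, n_signal_targets = 85,
                       n_noise_targets = 6, coeff_range = c(0.2, 2),
                       noise_sd = 0.05, bag_sd = 0.1,
                       day31_artifact = FALSE, lag_mixing = FALSE, seed = 1) {
  stopifnot(n_replicates >= 1, n_biomarkers >= 1, n_signal_targets >= 0,
            n_noise_targets >= 0, length(time_days) >= 2,
            all(diff(time_days) > 0), noise_sd >= 0, bag_sd >= 0,
            length(coeff_range) == 2, coeff_range[1] <= coeff_range[2])
  if (max(abs(coeff_range)) == 0)
    rbf_stop("coeff_range would make every signal target identically zero",
             "spec_error")
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate biomarker profiles for every replicate
#'
#' Each biomarker gets a deterministic three-phase piecewise-linear template
#' (two interior breakpoints drawn once per biomarker; alternately
#' glucose-like monotone decay and lactate-like monotone accumulation, with
#' the rapid middle phase staggered across biomarkers), multiplied per
#' replicate by a lognormal bag factor and perturbed by proportional
#' Gaussian measurement noise, truncated at 0.
#'
#' @param spec a [synth_spec()].
#' @return list with `profiles` (array biomarker x replicate x time),
#'   `templates` (matrix time x biomarker), `breakpoints` (2 x biomarker
#'   day values), `bag_factors` (per replicate; shared with
#'   [generate_targets()]), `biomarker_ids`.
#' @export
generate_biomarkers <- function(spec) {
  n_t <- length(spec$time_days)
  ids <- sprintf("bm%02d", seq_len(spec$n_biomarkers))
  with_seed(derive_seed(spec$seed, "biomarkers"), {
    templates <- matrix(0, n_t, spec$n_biomarkers, dimnames = list(NULL, ids))
    bps <- matrix(0, 2, spec$n_biomarkers, dimnames = list(NULL, ids))
    t_lo <- spec$time_days[1]
    t_hi <- spec$time_days[n_t]
    interior <- spec$time_days[seq(2, n_t - 1)]
    for (i in seq_len(spec$n_biomarkers)) {
      decreasing <- (i %% 2 == 1)            # alternate decay / accumulation
      scale <- stats::runif(1, 5, 15)
      # Different metabolites switch in different phases of the storage
      # lesion, so each template's rapid middle phase sits in its own
      # staggered time window (slow drift before, plateau after): this keeps
      # the five profiles shape-diverse and the mixing identifiable.
      ctr <- t_lo + (i - 0.5) / spec$n_biomarkers * (t_hi - t_lo)
      hw <- stats::runif(1, 0.07, 0.11) * (t_hi - t_lo)
      if (length(interior) >= 2) {
        bp1 <- interior[which.min(abs(interior - (ctr - hw)))]
        bp2 <- interior[which.min(abs(interior - (ctr + hw)))]
        if (bp2 <= bp1)                       # force two distinct grid knots
          bp2 <- interior[min(match(bp1, interior) + 1L, length(interior))]
        if (bp2 <= bp1) { bp1 <- interior[1]; bp2 <- interior[2] }
      } else {
        bp1 <- ctr - hw; bp2 <- ctr + hw
      }
      lo <- stats::runif(1, 0.02, 0.15)      # floor as fraction of the peak
      share <- stats::runif(1, 0.8, 0.95)    # change carried by the middle phase
      rest <- (1 - share) * stats::runif(1, 0.2, 0.8)
      fr <- 1 - cumsum(c(0, rest, share, 1 - share - rest)) * (1 - lo)
      if (!decreasing) fr <- rev(fr)
      templates[, i] <- stats::approx(c(t_lo, bp1, bp2, t_hi), scale * fr,
                                      xout = spec$time_days)$y
      bps[, i] <- c(bp1, bp2)
    }
    bag <- stats::rlnorm(spec$n_replicates, 0, spec$bag_sd)
    rep_ids <- sprintf("bag%02d", seq_len(spec$n_replicates))
    profiles <- array(0, dim = c(spec$n_biomarkers, spec$n_replicates, n_t),
                      dimnames = list(ids, rep_ids, NULL))
    for (i in seq_len(spec$n_biomarkers)) {
      for (r in seq_len(spec$n_replicates)) {
        clean <- templates[, i] * bag[r]
        # proportional measurement noise, the standard error model for
        # quantified metabolite concentrations
        profiles[i, r, ] <- pmax(clean * (1 + stats::rnorm(n_t, 0, spec$noise_sd)), 0)
      }
    }
    list(profiles = profiles, templates = templates, breakpoints = bps,
         bag_factors = stats::setNames(bag, rep_ids), biomarker_ids = ids)
  })
}

#' Generate target metabolites and assemble the full dataset
#'
#' Signal targets follow the static linear mixing truth
#' `y_r(t) = sum_i b*_i u_{i,r}(t) + e_r(t)` per replicate (with the
#' biomarkers optionally lagged one sample when `spec$lag_mixing`), with
#' `b*` drawn once per target from `coeff_range` and `e` proportional
#' Gaussian measurement noise at level `noise_sd`; noise targets are
#' positive noise about a constant with no biomarker dependence.  All values are truncated
#' at 0.  With `day31_artifact`, extracellular deviations from the
#' across-replicate mean at day 31 are inflated tenfold.
#'
#' @param spec a [synth_spec()].
#' @param biomarkers output of [generate_biomarkers()] under the same spec.
#' @return list with `dataset` (a [metab_dataset()]) and `ground_truth`
#'   (list: `targets` data.frame of `target_id, kind`; `coefficients`
#'   matrix biomarker x signal-target of true `b*`; `bag_factors`;
#'   `artifact_day`).
#' @export
generate_targets <- function(spec, biomarkers) {
  n_t <- length(spec$time_days)
  n_r <- spec$n_replicates
  rep_ids <- names(biomarkers$bag_factors)
  sig_ids <- sprintf("sig%03d", seq_len(spec$n_signal_targets))
  nse_ids <- sprintf("nse%03d", seq_len(spec$n_noise_targets))
  met_ids <- c(biomarkers$biomarker_ids, sig_ids, nse_ids)
  conc <- array(0, dim = c(length(met_ids), n_r, n_t),
                dimnames = list(met_ids, rep_ids, NULL))
  conc[biomarkers$biomarker_ids, , ] <- biomarkers$profiles
  # biomarkers measured extracellularly; targets alternate compartments
  comp <- c(rep("extracellular", spec$n_biomarkers),
            rep_len(c("intracellular", "extracellular"),
                    spec$n_signal_targets + spec$n_noise_targets))
  bstar <- matrix(0, spec$n_biomarkers, spec$n_signal_targets,
                  dimnames = list(biomarkers$biomarker_ids, sig_ids))
  u_eff <- biomarkers$profiles
  if (spec$lag_mixing) {
    u_eff[, , 2:n_t] <- biomarkers$profiles[, , 1:(n_t - 1), drop = FALSE]
    u_eff[, , 1] <- 0
  }
  with_seed(derive_seed(spec$seed, "targets"), {
    for (k in seq_len(spec$n_signal_targets)) {
      b <- stats::runif(spec$n_biomarkers, spec$coeff_range[1], spec$coeff_range[2])
      bstar[, k] <- b
      clean <- apply(u_eff, c(2, 3), function(u) sum(b * u))   # replicate x time
      noise <- matrix(stats::rnorm(n_r * n_t, 0, spec$noise_sd), n_r, n_t)
      conc[sig_ids[k], , ] <- pmax(clean * (1 + noise), 0)     # proportional noise
    }
    for (k in seq_len(spec$n_noise_targets)) {
      level <- stats::runif(1, 1, 10)
      noise <- matrix(stats::rnorm(n_r * n_t, 0, spec$noise_sd), n_r, n_t)
      conc[nse_ids[k], , ] <- pmax(level * (1 + noise), 0)
    }
    artifact_day <- NA_real_
    if (spec$day31_artifact && 31 %in% spec$time_days) {
      artifact_day <- 31
      t31 <- match(31, spec$time_days)
      extr <- met_ids[comp == "extracellular"]
      for (m in extr) {
        x <- conc[m, , t31]
        conc[m, , t31] <- pmax(mean(x) + 10 * (x - mean(x)), 0)
      }
    }
  })
  ds <- metab_dataset(conc, comp, spec$time_days, biomarkers$biomarker_ids)
  gt <- list(
    targets = data.frame(target_id = c(sig_ids, nse_ids),
                         kind = c(rep("signal", spec$n_signal_targets),
                                  rep("noise", spec$n_noise_targets)),
                         stringsAsFactors = FALSE),
    coefficients = bstar,
    bag_factors = biomarkers$bag_factors,
    artifact_day = artifact_day)
  list(dataset = ds, ground_truth = gt)
}

#' Generate a complete synthetic dataset
#'
#' One-call wrapper: [generate_biomarkers()] then [generate_targets()].
#'
#' @param spec a [synth_spec()].
#' @return list with `dataset`, `ground_truth`, and the intermediate
#'   `biomarkers` object.
#' @export
generate_dataset <- function(spec = synth_spec()) {
  bm <- generate_biomarkers(spec)
  gt <- generate_targets(spec, bm)
  list(dataset = gt$dataset, ground_truth = gt$ground_truth, biomarkers = bm)
}

#' Write the generator's ground truth as sidecar CSVs
#'
#' @param ground_truth the `ground_truth` element of [generate_dataset()].
#' @param coeff_path CSV for `target_id,kind,biomarker_id,true_coefficient`
#'   (noise targets appear with empty biomarker and coefficient fields).
#' @param bag_path CSV for `replicate_id,bag_factor`.
#' @return invisibly, the two paths.
#' @export
write_ground_truth <- function(ground_truth, coeff_path, bag_path) {
  gt <- ground_truth
  sig <- gt$targets$target_id[gt$targets$kind == "signal"]
  rows <- list()
  for (s in sig) {
    rows[[s]] <- data.frame(target_id = s, kind = "signal",
                            biomarker_id = rownames(gt$coefficients),
                            true_coefficient = fmt_num(gt$coefficients[, s]),
                            stringsAsFactors = FALSE)
  }
  nse <- gt$targets$target_id[gt$targets$kind == "noise"]
  if (length(nse) > 0)
    rows[["noise"]] <- data.frame(target_id = nse, kind = "noise",
                                  biomarker_id = "", true_coefficient = "",
                                  stringsAsFactors = FALSE)
  utils::write.csv(do.call(rbind, rows), coeff_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(replicate_id = names(gt$bag_factors),
                              bag_factor = fmt_num(gt$bag_factors)),
                   bag_path, row.names = FALSE, quote = FALSE)
  invisible(c(coeff_path, bag_path))
}
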