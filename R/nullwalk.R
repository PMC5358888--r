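# Naive random-walk benchmark: an ensemble prediction is accepted as
# informative for a metabolite only when fewer than 5% of seeded random
# walks (zero-mean Gaussian increments, sigma estimated from the observed
# per-step changes, started from measured starting concentrations) score a
# lower SMAPE than the model's average prediction error.

#' Estimate the per-step standard deviation of a metabolite's changes
#'
#' Pools the consecutive differences `y_r(t+1) - y_r(t)` over the given
#' replicates and all grid steps, and returns their root mean square (the
#' standard deviation about an assumed zero mean).
#'
#' @param ds a `metab_dataset`.
#' @param replicate_ids replicates to pool (typically the testing half).
#' @param metabolite_id the metabolite.
#' @return non-negative scalar sigma.
#' @export
estimate_step_sigma <- function(ds, replicate_ids, metabolite_id) {
  if (length(ds$time_days) < 2)
    rbf_stop("need >= 2 time points to compute changes", "insufficient_data_error")
  x <- ds$conc[metabolite_id, replicate_ids, , drop = FALSE][1, , , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)   # single replicate
  d <- t(apply(x, 1, diff))
  sqrt(mean(d^2))
}

#' Simulate naive random-walk concentration profiles
#'
#' Each walk starts at a value drawn uniformly from `start_pool` and adds an
#' independent `Normal(0, sigma^2)` increment per grid interval (one step
#' per sample, unscaled by interval length, matching how sigma is estimated
#' from per-step differences on the same grid).  Negative values are
#' clipped to 0 by default so walks stay in SMAPE's domain.
#'
#' @param n_walks number of walks.
#' @param time_grid the sampling grid (length defines the walk length).
#' @param sigma per-step standard deviation (>= 0).
#' @param start_pool non-empty numeric pool of measured starting values.
#' @param seed integer seed; walks are deterministic given the seed.
#' @param clip_at_zero clip walks at 0 (default `TRUE`).
#' @return numeric matrix, `n_walks` x `length(time_grid)`.
#' @export
simulate_walks <- function(n_walks, time_grid, sigma, start_pool, seed,
                           clip_at_zero = TRUE) {
  stopifnot(n_walks >= 1, sigma >= 0, length(start_pool) >= 1)
  n_t <- length(time_grid)
  with_seed(seed, {
    w <- matrix(0, n_walks, n_t)
    w[, 1] <- start_pool[sample.int(length(start_pool), n_walks, replace = TRUE)]
    if (clip_at_zero) w[, 1] <- pmax(w[, 1], 0)
    for (t in seq_len(n_t - 1L)) {
      step <- stats::rnorm(n_walks, 0, sigma)
      w[, t + 1L] <- w[, t] + step
      if (clip_at_zero) w[, t + 1L] <- pmax(w[, t + 1L], 0)
    }
    w
  })
}

# mean-over-replicates SMAPE of every walk against the measured profiles,
# vectorized over walks; measured is replicates x times
walk_scores <- function(walks, measured, epsilon = 1e-12) {
  scores <- matrix(0, nrow(walks), nrow(measured))
  for (r in seq_len(nrow(measured))) {
    y <- matrix(measured[r, ], nrow(walks), ncol(walks), byrow = TRUE)
    scores[, r] <- rowMeans(abs(walks - y) / pmax(walks + y, epsilon))
  }
  rowMeans(scores)
}

#' Benchmark a model score against random-walk profiles
#'
#' Each walk is scored by its mean SMAPE against the measured testing
#' profiles (the same aggregation as the model's score); the empirical
#' p-value is the fraction of walks with a strictly lower score, and the
#' metabolite is called significant when `p < 0.05` — i.e. fewer than 5% of
#' walks outperform the trained model.
#'
#' @param walks walk matrix from [simulate_walks()].
#' @param measured numeric matrix of measured testing profiles, replicates x
#'   times (a vector is treated as one replicate).
#' @param model_score the model's mean SMAPE over testing replicates.
#' @param metabolite_id optional id to attach.
#' @return list of class `benchmark_result`: `metabolite_id`, `model_score`,
#'   `walk_scores`, `p_empirical`, `significant`.
#' @export
benchmark_metabolite <- function(walks, measured, model_score,
                                 metabolite_id = NA_character_) {
  if (is.vector(measured)) measured <- matrix(measured, nrow = 1)
  if (ncol(measured) != ncol(walks))
    rbf_stop("measured profiles and walks are on different grids",
             "alignment_error")
  ws <- walk_scores(walks, measured)
  p <- sum(ws < model_score) / length(ws)
  structure(list(metabolite_id = metabolite_id, model_score = model_score,
                 walk_scores = ws, p_empirical = p,
                 significant = p < 0.05, n_walks = length(ws)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result %s: model SMAPE %.4f, p = %.4f (%ssignificant, %d walks)\n",
              x$metabolite_id, x$model_score, x$p_empirical,
              if (x$significant) "" else "not ", x$n_walks))
  invisible(x)
}

#' Run the random-walk benchmark for every predicted metabolite
#'
#' For each metabolite: estimates sigma from the testing replicates, draws
#' walks started from the pool of measured first-time-point testing values,
#' and compares against the model's mean consensus SMAPE.  Each metabolite
#' uses a seed derived from `(seed, metabolite index)` so results do not
#' depend on processing order.
#'
#' @param ds a `metab_dataset`.
#' @param split a `split_assignment`.
#' @param predictions named list of `prediction_result` (names = metabolite
#'   ids) supplying the model scores.
#' @param n_walks walks per metabolite (default 10000).
#' @param seed global benchmark seed.
#' @return data.frame, one row per metabolite: `metabolite_id,
#'   model_mean_smape, walk_smape_q05, walk_smape_median, p_empirical,
#'   significant, n_walks, sigma`.
#' @export
benchmark_dataset <- function(ds, split, predictions, n_walks = 10000, seed = 1) {
  te <- split$testing_replicates
  mets <- names(predictions)
  met_index <- match(mets, ds$metabolites$metabolite_id)
  rows <- lapply(seq_along(mets), function(k) {
    m <- mets[k]
    sigma <- estimate_step_sigma(ds, te, m)
    measured <- ds$conc[m, te, , drop = FALSE][1, , ]
    if (is.null(dim(measured))) measured <- matrix(measured, nrow = length(te))
    walks <- simulate_walks(n_walks, ds$time_days, sigma,
                            start_pool = measured[, 1],
                            seed = derive_seed(seed, "walks", met_index[k]))
    br <- benchmark_metabolite(walks, measured,
                               predictions[[m]]$summary_smape, m)
    data.frame(metabolite_id = m, model_mean_smape = br$model_score,
               walk_smape_q05 = stats::quantile(br$walk_scores, 0.05, names = FALSE),
               walk_smape_median = stats::median(br$walk_scores),
               p_empirical = br$p_empirical, significant = br$significant,
               n_walks = br$n_walks, sigma = sigma, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
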