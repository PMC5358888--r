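# Output-Error (OE) model representation, simulation and estimation.
#
# The model class is y(t) = sum_i B_i(q)/F_i(q) u_i(t - nk) + e(t) with
# B(q) = b1 + b2 q^-1 + ... + b_nb q^(-nb+1) and
# F(q) = 1 + f1 q^-1 + ... + f_nf q^-nf, where q^-1 is the one-sample delay
# (q^-1 x)(t) = x(t-1) acting on sample index, not clock time.  Estimation is
# provided for the nf = 0 (finite-impulse-response) family, where least
# squares has a closed form; simulation supports nf > 0.

#' Specify an Output-Error model structure
#'
#' @param n_inputs number of measured input signals (biomarkers).
#' @param nb order of the B (numerator) polynomial per input; `nb = 1` is a
#'   static gain.
#' @param nf order of the F (denominator) polynomial per input; `nf = 0`
#'   reduces the model to finite impulse response.
#' @param nk input delay in samples per input.
#' @param include_intercept add a constant term to the output equation
#'   (default `FALSE`: the model is a pure input mix, so with `nb = 1`,
#'   `nf = 0`, `nk = 0` it is multiple regression through the origin).
#' @return an object of class `oe_spec`.
#' @export
oe_spec <- function(n_inputs, nb = 1, nf = 0, nk = 0, include_intercept = FALSE) {
  stopifnot(n_inputs >= 1, nb >= 1, nf >= 0, nk >= 0,
            is.logical(include_intercept))
  structure(list(n_inputs = as.integer(n_inputs), nb = as.integer(nb),
                 nf = as.integer(nf), nk = as.integer(nk),
                 include_intercept = include_intercept),
            class = "oe_spec")
}

n_free_coefficients <- function(spec) {
  spec$n_inputs * spec$nb + as.integer(spec$include_intercept)
}

#' Construct an OE model from known coefficients
#'
#' @param spec an [oe_spec()].
#' @param b numeric matrix `nb x n_inputs` (or vector when `nb = 1`) of
#'   numerator coefficients, column i belonging to input i.
#' @param f numeric matrix `nf x n_inputs` of denominator coefficients
#'   (omit when `nf = 0`).
#' @param intercept constant term (must be 0 unless the spec enables it).
#' @param input_ids ordered input identifiers.
#' @return an object of class `oe_model`.
#' @export
oe_model <- function(spec, b, f = NULL, intercept = 0,
                     input_ids = paste0("u", seq_len(spec$n_inputs))) {
  b <- matrix(b, nrow = spec$nb, ncol = spec$n_inputs)
  if (spec$nf > 0) {
    f <- matrix(f, nrow = spec$nf, ncol = spec$n_inputs)
  } else {
    f <- matrix(numeric(0), nrow = 0, ncol = spec$n_inputs)
  }
  if (!spec$include_intercept && intercept != 0)
    rbf_stop("intercept given but spec$include_intercept is FALSE", "usage_error")
  stopifnot(length(input_ids) == spec$n_inputs)
  structure(list(spec = spec, b = b, f = f, intercept = intercept,
                 input_ids = as.character(input_ids)),
            class = "oe_model")
}

#' @export
print.oe_model <- function(x, ...) {
  cat(sprintf("oe_model: %d inputs, nb=%d nf=%d nk=%d%s\n", x$spec$n_inputs,
              x$spec$nb, x$spec$nf, x$spec$nk,
              if (x$spec$include_intercept) " + intercept" else ""))
  cat("  b:", paste(signif(as.vector(x$b), 5), collapse = " "), "\n")
  if (x$spec$nf > 0)
    cat("  f:", paste(signif(as.vector(x$f), 5), collapse = " "), "\n")
  invisible(x)
}

# lag a signal by k samples, padding with zeros (zero initial conditions)
lag_zero <- function(x, k) {
  n <- length(x)
  if (k <= 0) return(x)
  c(rep(0, min(k, n)), x[seq_len(max(n - k, 0))])
}

as_input_matrix <- function(inputs, spec) {
  u <- as.matrix(inputs)
  if (ncol(u) != spec$n_inputs)
    rbf_stop(sprintf("expected %d input signals, got %d", spec$n_inputs, ncol(u)),
             "alignment_error")
  u
}

#' Simulate the noise-free response of an OE model
#'
#' Runs the recursion per input with zero initial conditions (pre-sample
#' values of inputs and filter states are 0) and sums the filtered inputs:
#' each input contributes `w_i(t) = -sum_k f_ik w_i(t-k) + sum_j b_ij
#' u_i(t - nk - j + 1)`.
#'
#' @param model an [oe_model()].
#' @param inputs numeric matrix, time points x inputs, columns in
#'   `model$input_ids` order (all inputs share one sample grid).
#' @return numeric vector of predicted outputs, one per sample.
#' @export
simulate_oe <- function(model, inputs) {
  spec <- model$spec
  u <- as_input_matrix(inputs, spec)
  n <- nrow(u)
  if (n <= max(spec$nk + spec$nb - 1, spec$nf))
    rbf_stop("sample grid too short for the model orders", "insufficient_data_error")
  y <- rep(model$intercept, n)
  for (i in seq_len(spec$n_inputs)) {
    v <- rep(0, n)
    for (j in seq_len(spec$nb))
      v <- v + model$b[j, i] * lag_zero(u[, i], spec$nk + j - 1)
    if (spec$nf > 0) {
      w <- numeric(n)
      for (t in seq_len(n)) {
        acc <- v[t]
        for (k in seq_len(spec$nf))
          if (t - k >= 1) acc <- acc - model$f[k, i] * w[t - k]
        w[t] <- acc
      }
      v <- w
    }
    y <- y + v
  }
  y
}

# regressor matrix for the FIR (nf = 0) family; column order is input-major:
# b_{1,1..nb}, b_{2,1..nb}, ..., then the intercept column if enabled
fir_regressors <- function(spec, u) {
  cols <- list()
  for (i in seq_len(spec$n_inputs))
    for (j in seq_len(spec$nb))
      cols[[length(cols) + 1L]] <- lag_zero(u[, i], spec$nk + j - 1)
  if (spec$include_intercept) cols[[length(cols) + 1L]] <- rep(1, nrow(u))
  do.call(cbind, cols)
}

#' Fit an OE model of the FIR family by least squares
#'
#' Minimizes the output-error sum of squares `sum_t (y(t) - yhat(t))^2` in
#' closed form: with `nf = 0` the prediction is linear in the coefficients,
#' so the fit is the regression of the output on (lagged) inputs, pre-sample
#' lags taken as zero to match [simulate_oe()].  A rank-deficient regressor
#' matrix yields the minimum-norm solution with a warning.
#'
#' @param spec an [oe_spec()] with `nf = 0`.
#' @param inputs numeric matrix, time points x inputs.
#' @param output numeric vector of measured outputs, same grid.
#' @param input_ids identifiers for the input columns.
#' @return a fitted [oe_model()].
#' @export
fit_oe <- function(spec, inputs, output,
                   input_ids = colnames(inputs)) {
  if (spec$nf > 0)
    rbf_stop("estimation is only supported for nf = 0 (FIR family)",
             "unsupported_spec_error")
  u <- as_input_matrix(inputs, spec)
  y <- as.numeric(output)
  if (length(y) != nrow(u))
    rbf_stop("output and inputs have different grid lengths", "alignment_error")
  p <- n_free_coefficients(spec)
  if (length(y) < p)
    rbf_stop(sprintf("need >= %d samples to estimate %d coefficients", p, p),
             "insufficient_data_error")
  X <- fir_regressors(spec, u)
  qx <- qr(X)
  if (qx$rank < p) {
    warning("rank-deficient regressors; returning the minimum-norm solution")
    sv <- svd(X)
    keep <- sv$d > max(sv$d) * 1e-10
    theta <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
    theta <- as.numeric(theta)
  } else {
    theta <- qr.coef(qx, y)
  }
  if (is.null(input_ids)) input_ids <- paste0("u", seq_len(spec$n_inputs))
  b <- matrix(theta[seq_len(spec$n_inputs * spec$nb)],
              nrow = spec$nb, ncol = spec$n_inputs)
  intercept <- if (spec$include_intercept) theta[p] else 0
  oe_model(spec, b, intercept = intercept, input_ids = input_ids)
}

#' Select an OE model order by cross-validated prediction error
#'
#' Fits each candidate structure under leave-one-replicate-out
#' cross-validation on the training replicates (one model per held-in
#' replicate, median-consensus prediction for the held-out replicate over
#' all target metabolites) and scores by mean SMAPE.  Ties go to the
#' structure with fewer free coefficients, then to candidate order.
#'
#' @param candidate_specs list of [oe_spec()] objects (>= 1).
#' @param ds a `metab_dataset`.
#' @param training_replicates replicate ids to cross-validate within.
#' @param target_pool metabolites to score (default all targets).
#' @return list with `best_spec` and `table` (data.frame of candidate,
#'   n_coefficients, mean_smape).
#' @export
select_model_order <- function(candidate_specs, ds, training_replicates,
                               target_pool = target_ids(ds)) {
  stopifnot(length(candidate_specs) >= 1)
  scores <- vapply(candidate_specs, function(sp) {
    loro_cv_smape(ds, training_replicates, ds$biomarker_ids, sp, target_pool)$mean_smape
  }, numeric(1))
  ncoef <- vapply(candidate_specs, n_free_coefficients, integer(1))
  tab <- data.frame(
    candidate = vapply(candidate_specs, function(sp)
      sprintf("nb=%d nf=%d nk=%d%s", sp$nb, sp$nf, sp$nk,
              if (sp$include_intercept) "+c" else ""), character(1)),
    n_coefficients = ncoef, mean_smape = scores, stringsAsFactors = FALSE)
  best <- order(scores, ncoef, seq_along(candidate_specs))[1]
  list(best_spec = candidate_specs[[best]], table = tab)
}

#' Write an OE model to a plain-text file
#'
#' Coefficients are stored at full precision (17 significant digits) so a
#' read/write cycle is exact.
#'
#' @param model an [oe_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_oe_model <- function(model, path) {
  sp <- model$spec
  lines <- c(
    sprintf("n_inputs: %d", sp$n_inputs),
    sprintf("nb: %d", sp$nb),
    sprintf("nf: %d", sp$nf),
    sprintf("nk: %d", sp$nk),
    sprintf("include_intercept: %s", sp$include_intercept),
    sprintf("input_ids: %s", paste(model$input_ids, collapse = ",")),
    sprintf("b: %s", paste(fmt_num(as.vector(model$b)), collapse = ",")),
    sprintf("f: %s", paste(fmt_num(as.vector(model$f)), collapse = ",")),
    sprintf("intercept: %s", fmt_num(model$intercept)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an OE model written by [write_oe_model()]
#' @param path model file path.
#' @return an [oe_model()].
#' @export
read_oe_model <- function(path) {
  kv <- strsplit(readLines(path), ": ", fixed = TRUE)
  val <- stats::setNames(vapply(kv, function(x)
    if (length(x) > 1) x[2] else "", character(1)),
    vapply(kv, `[`, character(1), 1))
  split_num <- function(s) if (nzchar(s)) as.numeric(strsplit(s, ",")[[1]]) else numeric(0)
  spec <- oe_spec(as.integer(val["n_inputs"]), as.integer(val["nb"]),
                  as.integer(val["nf"]), as.integer(val["nk"]),
                  as.logical(val["include_intercept"]))
  oe_model(spec, split_num(val["b"]),
           f = if (spec$nf > 0) split_num(val["f"]) else NULL,
           intercept = as.numeric(val["intercept"]),
           input_ids = strsplit(val[["input_ids"]], ",")[[1]])
}
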