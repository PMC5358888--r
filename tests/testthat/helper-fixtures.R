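# Small fixtures built in code.

# tiny hand-specified dataset: values indexed [metabolite, replicate, time]
tiny_dataset <- function(n_met = 2, n_rep = 2, n_time = 3,
                         biomarkers = "m1", values = NULL) {
  mets <- paste0("m", seq_len(n_met))
  reps <- paste0("r", seq_len(n_rep))
  if (is.null(values))
    values <- array(seq_len(n_met * n_rep * n_time), c(n_met, n_rep, n_time))
  dimnames(values) <- list(mets, reps, NULL)
  metab_dataset(values, rep_len(c("extracellular", "intracellular"), n_met),
                seq_len(n_time) - 1, biomarkers)
}

# small synthetic study, cheap enough for tight loops
small_spec <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_replicates = 8, n_signal_targets = 6, n_noise_targets = 2,
                   seed = seed)
  do.call(synth_spec, utils::modifyList(defaults, args))
}

# independent least-squares oracle: explicit normal equations
normal_equations <- function(X, y) as.numeric(solve(crossprod(X), crossprod(X, y)))
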