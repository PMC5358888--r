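test_that("ensembles have one member per training replicate, in order", {
  g <- generate_dataset(synth_spec(seed = 17, n_signal_targets = 3,
                                   n_noise_targets = 0))
  sp <- split_replicates(g$dataset, 17)
  em <- train_ensemble(g$dataset, sp, "sig001")
  expect_length(em$members, 10)
  expect_identical(names(em$members), sp$training_replicates)
  expect_error(train_ensemble(g$dataset, sp, "bm01"), class = "rbf_usage_error")
  # fit errors carry target and replicate context
  bad <- g$dataset
  expect_error(
    train_ensemble(exclude_timepoints(bad, bad$time_days[-(1:3)]), sp, "sig001"),
    "sig001.*bag")
})

test_that("identical replicates give identical members; noiseless data gives exact recovery", {
  g <- generate_dataset(small_spec(seed = 18, noise_sd = 0, bag_sd = 0))
  sp <- split_replicates(g$dataset, 18)
  for (tgt in c("sig001", "sig004")) {
    em <- train_ensemble(g$dataset, sp, tgt)
    bhat <- vapply(em$members, function(m) as.vector(m$b), numeric(5))
    expect_equal(max(apply(bhat, 1, stats::sd)), 0)
    expect_lt(max(abs(bhat - g$ground_truth$coefficients[, tgt])), 1e-6)
  }
})

test_that("consensus is the per-time-point median of member predictions", {
  # members built so predictions at the two times are (1,1), (2,5), (9,3):
  # with inputs u1 = (1,0), u2 = (0,1), member coefficients ARE predictions
  spec <- oe_spec(2)
  em <- structure(list(
    target_id = "t", spec = spec, biomarker_ids = c("u1", "u2"),
    members = list(a = oe_model(spec, c(1, 1)), b = oe_model(spec, c(2, 5)),
                   c = oe_model(spec, c(9, 3)))), class = "ensemble_model")
  u <- cbind(c(1, 0), c(0, 1))
  pr <- predict_consensus(em, u)
  expect_equal(pr$replicates[[1]]$consensus, c(2, 3))

  # identical members: consensus equals any single member's prediction
  em$members <- em$members[c(1, 1, 1)]
  expect_equal(predict_consensus(em, u)$replicates[[1]]$consensus, c(1, 1))

  # even member count: mean of the two central values
  em$members <- list(oe_model(spec, c(1, 0)), oe_model(spec, c(2, 0)),
                     oe_model(spec, c(4, 0)), oe_model(spec, c(10, 0)))
  expect_equal(predict_consensus(em, u)$replicates[[1]]$consensus[1], 3)
})

test_that("consensus is order-invariant and bounded by the member envelope", {
  g <- generate_dataset(small_spec(seed = 19))
  sp <- split_replicates(g$dataset, 19)
  em <- train_ensemble(g$dataset, sp, "sig002")
  pr <- predict_targets(em, g$dataset, sp$testing_replicates)
  for (z in pr$replicates) {
    expect_true(all(z$consensus >= apply(z$member_predictions, 2, min) - 1e-12))
    expect_true(all(z$consensus <= apply(z$member_predictions, 2, max) + 1e-12))
  }
  em_rev <- em
  em_rev$members <- rev(em$members)
  pr_rev <- predict_targets(em_rev, g$dataset, sp$testing_replicates)
  expect_equal(pr_rev$replicates[[1]]$consensus, pr$replicates[[1]]$consensus)
})

test_that("the median consensus shrugs off a grossly corrupted member", {
  g <- generate_dataset(synth_spec(seed = 31, n_signal_targets = 4,
                                   n_noise_targets = 0))
  sp <- split_replicates(g$dataset, 31)
  em <- train_ensemble(g$dataset, sp, "sig001")
  u <- biomarker_matrix(g$dataset, sp$testing_replicates[1])
  before <- predict_consensus(em, u)$replicates[[1]]

  # corrupt a member sitting strictly above the central pair at every time
  # point: inflating values already above the center cannot move the median
  preds <- before$member_predictions
  ranks <- apply(preds, 2, rank)
  above <- which(apply(ranks, 1, min) >= nrow(preds) / 2 + 2)
  expect_gt(length(above), 0)
  em_bad <- em
  em_bad$members[[above[1]]]$b <- em$members[[above[1]]]$b * 1000
  after <- predict_consensus(em_bad, u)$replicates[[1]]
  expect_identical(after$consensus, before$consensus)

  # any single corrupted member leaves the consensus inside the envelope of
  # the remaining healthy members (breakdown robustness), unlike the mean
  em_bad2 <- em
  em_bad2$members[[1]]$b <- em$members[[1]]$b * 1000
  after2 <- predict_consensus(em_bad2, u)$replicates[[1]]
  healthy <- preds[-1, , drop = FALSE]
  expect_true(all(after2$consensus <= apply(healthy, 2, max) + 1e-9))
  expect_true(all(after2$consensus >= apply(healthy, 2, min) - 1e-9))
  expect_gt(max(colMeans(after2$member_predictions)), 50 * max(before$consensus))
})

test_that("prediction never sees measured targets and scores against them when given", {
  g <- generate_dataset(small_spec(seed = 21))
  sp <- split_replicates(g$dataset, 21)
  em <- train_ensemble(g$dataset, sp, "sig003")
  pr <- predict_targets(em, g$dataset, sp$testing_replicates)
  expect_length(pr$replicates, length(sp$testing_replicates))
  smapes <- vapply(pr$replicates, `[[`, numeric(1), "smape")
  expect_true(all(smapes >= 0 & smapes <= 1))
  expect_equal(pr$summary_smape, mean(smapes))
  # without measurements the same predictions come back unscored
  u <- lapply(sp$testing_replicates, function(r) biomarker_matrix(g$dataset, r))
  pr2 <- predict_consensus(em, u)
  expect_true(is.na(pr2$summary_smape))
  expect_equal(pr2$replicates[[1]]$consensus, pr$replicates[[1]]$consensus)
})

test_that("ensembles round-trip through the model-file directory format", {
  g <- generate_dataset(small_spec(seed = 22))
  sp <- split_replicates(g$dataset, 22)
  em <- train_ensemble(g$dataset, sp, "sig001")
  dir <- withr::local_tempdir()
  write_ensemble(em, dir)
  em2 <- read_ensemble(dir, "sig001")
  expect_identical(names(em2$members), names(em$members))
  for (r in names(em$members))
    expect_identical(em2$members[[r]]$b, em$members[[r]]$b)
  u <- biomarker_matrix(g$dataset, sp$testing_replicates[1])
  expect_equal(predict_consensus(em2, u)$replicates[[1]]$consensus,
               predict_consensus(em, u)$replicates[[1]]$consensus)
})
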