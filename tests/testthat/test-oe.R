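test_that("simulation reproduces hand-computed static and delayed responses", {
  # static mix: y = 2*u1 - u2
  m <- oe_model(oe_spec(2), b = c(2, -1))
  expect_equal(simulate_oe(m, cbind(c(1, 2, 3), c(1, 1, 1))), c(1, 3, 5))
  # pure one-sample delay with zero initial condition
  m2 <- oe_model(oe_spec(1, nk = 1), b = 1)
  expect_equal(simulate_oe(m2, cbind(c(4, 5, 6))), c(0, 4, 5))
  # linearity in b
  u <- cbind(sin(1:10), cos(1:10) + 2)
  m3 <- oe_model(oe_spec(2), b = c(0.3, 1.7))
  m3s <- oe_model(oe_spec(2), b = 2.5 * c(0.3, 1.7))
  expect_equal(simulate_oe(m3s, u), 2.5 * simulate_oe(m3, u), tolerance = 1e-12)
})

test_that("rational-filter simulation matches the impulse-response oracle", {
  # nf = 1, nb = 1: impulse response h_k = b1 * (-f1)^k, so the output is
  # the explicit convolution sum — an independent evaluation of B/F
  withr::with_seed(21, {
    for (rep in 1:5) {
      b1 <- stats::rnorm(1); f1 <- stats::runif(1, -0.8, 0.8)
      u <- stats::rnorm(15)
      m <- oe_model(oe_spec(1, nf = 1), b = b1, f = f1)
      h <- b1 * (-f1)^(0:14)
      oracle <- vapply(1:15, function(t) sum(h[1:t] * u[t:1]), numeric(1))
      expect_equal(simulate_oe(m, cbind(u)), oracle, tolerance = 1e-10)
    }
  })
})

test_that("least-squares fit matches the normal-equations oracle", {
  spec <- oe_spec(5)
  withr::with_seed(31, {
    for (rep in 1:10) {
      U <- matrix(stats::runif(13 * 5, 0, 10), 13, 5)
      y <- stats::rnorm(13, mean = 5)
      fit <- fit_oe(spec, U, y)
      expect_equal(as.vector(fit$b), normal_equations(U, y), tolerance = 1e-8)
      # residuals orthogonal to every regressor column
      r <- y - simulate_oe(fit, U)
      expect_lt(max(abs(crossprod(U, r))), 1e-8 * max(abs(crossprod(U, y))))
    }
  })
})

test_that("fit is exact on noiseless data and matches lm through the origin", {
  withr::with_seed(32, {
    U <- matrix(stats::runif(13 * 2, 1, 10), 13, 2)
    y <- as.numeric(U %*% c(2, -0.5))
    fit <- fit_oe(oe_spec(2), U, y)
    expect_equal(as.vector(fit$b), c(2, -0.5), tolerance = 1e-8)

    # the five-biomarker static structure is regression through the origin
    U5 <- matrix(stats::runif(13 * 5, 0, 10), 13, 5)
    y5 <- stats::rnorm(13, 5)
    fit5 <- fit_oe(oe_spec(5), U5, y5)
    expect_length(as.vector(fit5$b), 5)
    expect_equal(as.vector(fit5$b), unname(stats::coef(stats::lm(y5 ~ 0 + U5))),
                 tolerance = 1e-10)
    # and with the intercept flag it matches ordinary lm
    fitc <- fit_oe(oe_spec(5, include_intercept = TRUE), U5, y5)
    lmc <- unname(stats::coef(stats::lm(y5 ~ U5)))
    expect_equal(c(fitc$intercept, as.vector(fitc$b)), lmc, tolerance = 1e-10)
  })
})

test_that("fitted coefficients beat any random coefficient vector in SSE", {
  withr::with_seed(33, {
    U <- matrix(stats::runif(14 * 3, 0, 5), 14, 3)
    y <- as.numeric(U %*% c(1, 2, 3)) + stats::rnorm(14)
    fit <- fit_oe(oe_spec(3), U, y)
    sse_fit <- sum((y - simulate_oe(fit, U))^2)
    for (k in 1:100) {
      alt <- oe_model(oe_spec(3), b = as.vector(fit$b) + stats::rnorm(3, 0, 0.5))
      expect_lte(sse_fit, sum((y - simulate_oe(alt, U))^2))
    }
  })
})

test_that("lagged regressors use zero initial conditions consistently", {
  # nk = 1: fitting y(t) = b * u(t-1) built with a leading zero must agree
  # with simulate_oe on the training window
  withr::with_seed(34, {
    u <- stats::runif(12, 1, 4)
    y <- 3 * c(0, u[-12])
    fit <- fit_oe(oe_spec(1, nk = 1), cbind(u), y)
    expect_equal(as.vector(fit$b), 3, tolerance = 1e-10)
    expect_equal(simulate_oe(fit, cbind(u)), y, tolerance = 1e-10)
  })
})

test_that("degenerate and invalid estimation problems are handled", {
  U <- matrix(stats::runif(10), 5, 2)
  expect_error(fit_oe(oe_spec(2, nf = 1), U, stats::rnorm(5)),
               class = "rbf_unsupported_spec_error")
  expect_error(fit_oe(oe_spec(2), U[1:2, ], stats::rnorm(5)),
               class = "rbf_alignment_error")
  expect_error(fit_oe(oe_spec(2, nb = 3), U, stats::rnorm(5)),
               class = "rbf_insufficient_data_error")
  # duplicated input column: minimum-norm solution, with a warning
  Ud <- cbind(U[, 1], U[, 1])
  y <- 2 * U[, 1]
  expect_warning(fitd <- fit_oe(oe_spec(2), Ud, y), "minimum-norm")
  expect_equal(as.vector(fitd$b), c(1, 1), tolerance = 1e-8)
  expect_equal(simulate_oe(fitd, Ud), y, tolerance = 1e-8)
})

test_that("model files round-trip exactly", {
  spec <- oe_spec(3, nb = 2, nk = 1, include_intercept = TRUE)
  m <- oe_model(spec, b = stats::rnorm(6), intercept = pi,
                input_ids = c("glc", "lac", "hyp"))
  path <- withr::local_tempfile(fileext = ".oe")
  write_oe_model(m, path)
  m2 <- read_oe_model(path)
  expect_identical(m2$b, m$b)
  expect_identical(m2$intercept, m$intercept)
  expect_identical(m2$input_ids, m$input_ids)
  expect_identical(unclass(m2$spec), unclass(m$spec))
})

test_that("order selection prefers the true simple structure", {
  # data generated with a static (nb = 1) truth: the nb = 1 candidate should
  # win the CV comparison in a majority of seeded repetitions
  wins <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    g <- generate_dataset(small_spec(seed = s, n_biomarkers = 2,
                                     n_signal_targets = 4, n_noise_targets = 0))
    sel <- select_model_order(list(oe_spec(2, nb = 1), oe_spec(2, nb = 3)),
                              g$dataset, g$dataset$replicate_ids[1:6])
    wins <- wins + (sel$best_spec$nb == 1)
  }
  expect_gt(wins, n_seeds / 2)

  # degenerate single candidate comes back unchanged, with its score
  g <- generate_dataset(small_spec(seed = 1, n_biomarkers = 2,
                                   n_signal_targets = 3, n_noise_targets = 0))
  one <- select_model_order(list(oe_spec(2)), g$dataset,
                            g$dataset$replicate_ids[1:4])
  expect_identical(one$best_spec, oe_spec(2))
  expect_equal(nrow(one$table), 1)

  # identical candidates: first wins by tie-break order
  two <- select_model_order(list(oe_spec(2), oe_spec(2)), g$dataset,
                            g$dataset$replicate_ids[1:4])
  expect_equal(two$table$mean_smape[1], two$table$mean_smape[2])
  expect_identical(two$best_spec, oe_spec(2))
})
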