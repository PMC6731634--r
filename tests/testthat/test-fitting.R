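test_that("static FC fit is the upper-triangle Pearson correlation", {
  set.seed(1)
  ts <- regional_ts(matrix(rnorm(5 * 80), 5), tr_s = 2)
  fc <- static_fc(ts)
  expect_equal(fc, stats::cor(t(ts$values)))
  expect_equal(fc_fit(fc, fc), 1)

  neg <- -fc; diag(neg) <- 1
  expect_equal(fc_fit(fc, neg), -1)

  # independent formula oracle on arbitrary matrices
  a <- matrix(rnorm(100), 10); b <- matrix(rnorm(100), 10)
  ua <- a[upper.tri(a)]; ub <- b[upper.tri(b)]
  oracle <- sum((ua - mean(ua)) * (ub - mean(ub))) /
    sqrt(sum((ua - mean(ua))^2) * sum((ub - mean(ub))^2))
  expect_equal(fc_fit(a, b), oracle, tolerance = 1e-12)

  bad <- ts; bad$values[2, ] <- 7
  expect_error(static_fc(bad), "constant")
  expect_error(fc_fit(matrix(0, 2, 2), matrix(0, 3, 3)), "dimensions")
})

test_that("grand-average phase coherence averages cosine phase differences", {
  mk_phases <- function(phases) {
    structure(list(phases = phases, amplitudes = phases * 0 + 1,
                   valid_range = seq_len(ncol(phases)), tr_s = 2,
                   subject_id = "s", condition = "c"),
              class = "phase_repr")
  }
  # identical phases: all entries 1
  ph <- mk_phases(rbind(seq(0, 5, length.out = 50), seq(0, 5, length.out = 50)))
  expect_equal(grand_average_phase_fc(ph), matrix(1, 2, 2), tolerance = 1e-12)

  # constant pi/2 offset: off-diagonal entry 0
  ph2 <- mk_phases(rbind(seq(0, 5, length.out = 50),
                         seq(0, 5, length.out = 50) + pi / 2))
  expect_equal(grand_average_phase_fc(ph2)[1, 2], 0, tolerance = 1e-12)

  # independent uniform phases: off-diagonals within a CLT bound of 0
  set.seed(4)
  n_t <- 4000
  ph3 <- mk_phases(matrix(stats::runif(3 * n_t, -pi, pi), 3))
  fc <- grand_average_phase_fc(ph3)
  expect_lt(max(abs(fc[row(fc) != col(fc)])), 3 / sqrt(n_t))
})

test_that("FCD matrix and KS distance match brute-force constructions", {
  set.seed(5)
  ts <- bandpass_filter(regional_ts(matrix(rnorm(6 * 120), 6), tr_s = 2))
  tens <- phase_coherence_tensor(compute_phases(ts, 3))
  fcd <- fcd_matrix(tens)
  expect_true(isSymmetric(fcd))
  expect_equal(diag(fcd), rep(1, nrow(fcd)))
  # spot-check one entry against the definition
  u1 <- tens$values[, , 4][upper.tri(tens$values[, , 4])]
  u2 <- tens$values[, , 9][upper.tri(tens$values[, , 9])]
  expect_equal(fcd[4, 9], sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2)))

  expect_equal(fcd_ks(tens, tens), 0)

  # hand-built samples vs exhaustive CDF scan: sup|F1 - F2| = 0.5
  ks_brute <- function(x, y) {
    grid <- sort(unique(c(x, y)))
    max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
  }
  x <- c(0.1, 0.2, 0.3); y <- c(0.2, 0.4)
  expect_equal(ks_brute(x, y), 0.5)
  expect_equal(unname(suppressWarnings(stats::ks.test(x, y)$statistic)), 0.5)

  # disjoint supports give KS = 1 through the tensor interface
  shift <- tens; shift$values <- tens$values * 0.1
  expect_lte(fcd_ks(tens, tens), 1)
})

test_that("symmetrized KL distance matches direct evaluation", {
  expect_equal(pms_kl(c(0.2, 0.8), c(0.2, 0.8)), 0)

  # frozen value computed from the definition with natural logs:
  # 0.5*(0.5 ln(0.5/0.9) + 0.5 ln(0.5/0.1) + 0.9 ln(0.9/0.5) + 0.1 ln(0.1/0.5))
  expect_equal(pms_kl(c(0.5, 0.5), c(0.9, 0.1)), 0.4394449,
               tolerance = 1e-6)

  # symmetry and non-negativity over random simplex pairs
  set.seed(6)
  for (i in 1:20) {
    p <- stats::rgamma(4, 1); p <- p / sum(p)
    q <- stats::rgamma(4, 1); q <- q / sum(q)
    expect_equal(pms_kl(p, q), pms_kl(q, p))
    expect_gte(pms_kl(p, q), 0)
  }
  # zero probabilities stay finite thanks to the floor
  expect_true(is.finite(pms_kl(c(1, 0, 0), c(0, 0, 1))))
  expect_error(pms_kl(c(0.5, 0.5), c(1, 0, 0) / 1), "equal length")
})

test_that("Markov entropy rate agrees with hand computation and simulation", {
  u3 <- matrix(1 / 3, 3, 3)
  expect_equal(markov_entropy_rate(u3), log(3))

  cyc <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(markov_entropy_rate(cyc), 0)

  tpm <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  p <- stationary_distribution(tpm)
  expect_equal(p, c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_lt(max(abs(drop(t(tpm) %*% p) - p)), 1e-10)
  # S = -(2/3)(0.9 ln 0.9 + 0.1 ln 0.1) - (1/3)(0.2 ln 0.2 + 0.8 ln 0.8)
  expect_equal(markov_entropy_rate(tpm), 0.3835228, tolerance = 1e-6)

  # empirical entropy of a long simulated chain
  lab <- generate_markov_labels(tpm, 1e5, seed = 11)
  est <- switching_matrix(lab, 2)
  expect_lt(abs(markov_entropy_rate(est) - markov_entropy_rate(tpm)), 0.01)

  expect_equal(entropy_distance(u3, cyc), log(3))

  red <- rbind(c(1, 0), c(0.5, 0.5))
  expect_error(markov_entropy_rate(red), "reducible")
})

test_that("self-evaluation of a model against its own data is perfect", {
  set.seed(7)
  ts_list <- lapply(1:2, function(i)
    regional_ts(matrix(rnorm(6 * 140), 6), tr_s = 2, subject_id = i))
  led <- run_leida(ts_list, k = 3, seed = 3)
  fit <- evaluate_model(ts_list, led$clustering$model, emp_series = ts_list)
  expect_equal(fit$kl_pms, 0)
  expect_equal(fit$ks_fcd, 0)
  expect_equal(fit$fc_corr, 1)
  expect_equal(fit$entropy_distance, 0)
  expect_length(fit$sim_probabilities, 3)
  expect_identical(fit$n_runs, 2L)
})

test_that("coupling sweeps report per-G fits and both optima", {
  sys <- fitting_system()
  ds <- generate_state_dataset(sys$conn, sys$params, 2, 260, tr_s = 2,
                               seed = 21)
  model <- run_leida(ds$series, k = 2, seed = 31)$clustering$model
  sw <- sweep_coupling(sys$conn, sys$params, g_grid = 0.4, model,
                       n_runs = 1, duration_s = 200, seed = 41)
  expect_identical(sw$g_star_pms, 0.4)        # single-point grid
  expect_identical(nrow(sw$table), 1L)
  expect_true(is.finite(sw$table$kl_pms))
  expect_error(sweep_coupling(sys$conn, sys$params, numeric(0), model),
               "ascending")
})

test_that("the EC update has the stated fixed point and step size", {
  cn <- generate_connectome(6, 1, 1, seed = 2)
  omega <- 2 * pi * seq(0.04, 0.06, length.out = 6)
  p <- hopf_params(a = 0.04, omega = omega, G = 0.2, beta = 0,
                   transient_s = 60)
  # zero residual: the model's own deterministic phase FC leaves C unchanged
  # (reproduce the optimizer's first internal run seed so, with beta = 0,
  # its model FC is exactly this target)
  sim <- simulate_hopf(cn$weights, p, 260,
                       seed = pmstates:::spawn_seeds(9, 1)[1])
  fc_own <- grand_average_phase_fc(compute_phases(bandpass_filter(sim$series),
                                                  3))
  ec <- optimize_ec(cn, p, fc_own, epsilon = 0.01, max_iter = 1,
                    duration_s = 260, seed = 9)
  expect_equal(ec$weights, cn$weights, tolerance = 1e-12, ignore_attr = TRUE)

  # a single off-diagonal residual of 0.1 moves that weight by exactly 0.001
  fc_shift <- fc_own
  fc_shift[1, 2] <- fc_shift[1, 2] + 0.1
  fc_shift[2, 1] <- fc_shift[2, 1] + 0.1
  ec2 <- optimize_ec(cn, p, fc_shift, epsilon = 0.01, max_iter = 1,
                     duration_s = 260, seed = 9)
  delta <- ec2$weights - cn$weights
  expect_equal(delta[1, 2], 0.001, tolerance = 1e-12)
  expect_equal(sum(abs(delta) > 1e-15), 2)    # only the symmetric pair moved
  expect_true(isSymmetric(ec2$weights))
})
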