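test_that("band-pass filter passes the band and rejects drift and DC", {
  # in-band 0.05 Hz sinusoid at TR = 2 s: amplitude preserved within 5%
  ts <- sinusoid_ts(rep(0.05, 2), tr_s = 2, n_t = 400)
  out <- bandpass_filter(ts, 0.02, 0.1)
  mid <- 100:300
  expect_equal(max(abs(out$values[1, mid])), 1, tolerance = 0.05)

  # 0.005 Hz drift: attenuated by at least 90%
  drift <- sinusoid_ts(rep(0.005, 2), tr_s = 2, n_t = 800)
  out <- bandpass_filter(drift, 0.02, 0.1)
  expect_lt(max(abs(out$values[1, 200:600])), 0.1)

  # constant input maps to ~0
  const <- regional_ts(matrix(3, 2, 100), tr_s = 2)
  expect_lt(max(abs(bandpass_filter(const)$values)), 1e-8)

  expect_error(bandpass_filter(ts, 0.02, 0.3), "Nyquist")
  expect_error(bandpass_filter(ts, 0.1, 0.02))
})

test_that("Hilbert phases advance at the carrier rate and keep offsets", {
  tr <- 2
  ts <- sinusoid_ts(rep(0.05, 2), tr_s = tr, n_t = 300)
  ph <- compute_phases(ts, trim = 3)
  wrap <- function(x) atan2(sin(x), cos(x))
  dphi <- wrap(diff(ph$phases[1, ph$valid_range]))
  expect_equal(mean(dphi), 2 * pi * 0.05 * tr, tolerance = 0.01)

  # identical regions: zero phase difference everywhere
  d <- ph$phases[1, ph$valid_range] - ph$phases[2, ph$valid_range]
  expect_lt(max(abs(wrap(d))), 1e-8)

  # sin vs cos: constant pi/2 offset
  tt <- (0:299) * tr
  ts2 <- regional_ts(rbind(cos(2 * pi * 0.05 * tt), sin(2 * pi * 0.05 * tt)),
                     tr_s = tr)
  ph2 <- compute_phases(ts2, trim = 5)
  mid <- ph2$valid_range[20:260]
  offs <- wrap(ph2$phases[1, mid] - ph2$phases[2, mid])
  expect_equal(mean(offs), pi / 2, tolerance = 0.02)

  expect_error(compute_phases(sinusoid_ts(0.05, n_t = 10), trim = 5), "trim")
})

test_that("phase-coherence entries are cosines of phase differences", {
  # hand-built phase representation with known offsets
  n_t <- 20
  phases <- rbind(rep(0.7, n_t), rep(0.7, n_t), rep(0.7 + pi / 2, n_t),
                  rep(0.7 + pi, n_t))
  pr <- structure(list(phases = phases, amplitudes = phases * 0 + 1,
                       valid_range = 1:n_t, tr_s = 2,
                       subject_id = "s", condition = "c"),
                  class = "phase_repr")
  tens <- phase_coherence_tensor(pr)
  expect_equal(tens$values[1, 2, 1], 1)            # equal phases
  expect_equal(tens$values[1, 3, 1], 0)            # 90 degrees
  expect_equal(tens$values[1, 4, 1], -1)           # anti-phase
  slice <- tens$values[, , 5]
  expect_true(isSymmetric(slice))
  expect_equal(diag(slice), rep(1, 4))
  expect_true(all(abs(slice) <= 1))
})

test_that("leading eigenvectors match an independent decomposition", {
  mk_tensor <- function(vals) {
    structure(list(values = vals, t_index = seq_len(dim(vals)[3]), tr_s = 2,
                   subject_id = "s", condition = "c"),
              class = "coherence_tensor")
  }
  # all-ones slice: elements 1/sqrt(N), eigenvalue N
  n <- 6
  ones <- array(1, c(n, n, 1))
  v <- leading_eigenvectors(mk_tensor(ones))$vectors[1, ]
  expect_equal(abs(v), rep(1 / sqrt(n), n), tolerance = 1e-10)

  # rank-1 slice v v^T returns +-v
  set.seed(1)
  u <- rnorm(n); u <- u / sqrt(sum(u^2))
  vv <- array(outer(u, u), c(n, n, 1))
  got <- leading_eigenvectors(mk_tensor(vv))$vectors[1, ]
  expect_equal(abs(got), abs(u), tolerance = 1e-10)

  # random symmetric slices against an SVD oracle
  set.seed(2)
  for (i in 1:5) {
    s <- matrix(rnorm(n * n), n); s <- (s + t(s)) / 2; diag(s) <- 1
    got <- leading_eigenvectors(mk_tensor(array(s, c(n, n, 1))))$vectors[1, ]
    sv <- svd(s)
    oracle <- sv$u[, which.max(sv$d)]
    expect_lt(min(sum((got - oracle)^2), sum((got + oracle)^2)), 1e-16)
  }

  # unit norm and sign convention on realistic data
  ts <- bandpass_filter(regional_ts(matrix(rnorm(8 * 150), 8), tr_s = 2))
  eig <- leading_eigenvectors(phase_coherence_tensor(compute_phases(ts, 3)))
  expect_equal(sqrt(rowSums(eig$vectors^2)), rep(1, nrow(eig$vectors)),
               tolerance = 1e-9)
  ok <- apply(eig$vectors, 1, function(v) {
    np <- sum(v > 0); nn <- sum(v < 0)
    if (np != nn) nn > np else v[which.max(abs(v))] < 0
  })
  expect_true(all(ok))

  asym <- array(matrix(rnorm(36), 6), c(6, 6, 1))
  expect_error(leading_eigenvectors(mk_tensor(asym)), "asymmetric")
})

test_that("k-means substates recover planted clusters deterministically", {
  fx <- generate_eigenvector_clusters(k = 3, n_regions = 12, n_samples = 120,
                                      separation = 10, seed = 4)
  cl <- cluster_states(fx$vectors, k = 3, n_restarts = 10, seed = 1)
  expect_gte(label_agreement(unlist(cl$labels), fx$labels, 3), 0.99)

  cl2 <- cluster_states(fx$vectors, k = 3, n_restarts = 10, seed = 1)
  expect_identical(cl$labels, cl2$labels)

  one <- cluster_states(fx$vectors, k = 1, seed = 1)
  expect_equal(one$centroids[1, ], colMeans(fx$vectors), tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(cluster_states(fx$vectors[1:2, ], k = 5, seed = 1), "exceeds")
})

test_that("silhouette table points at the planted cluster count", {
  fx <- generate_eigenvector_clusters(k = 3, n_regions = 10, n_samples = 150,
                                      separation = 8, seed = 6)
  tab <- select_k(fx$vectors, k_range = 2:6, n_restarts = 10, seed = 2)
  expect_identical(attr(tab, "best_k"), 3L)

  # near-uniform directions: silhouette low for every k
  un <- generate_eigenvector_clusters(k = 1, n_regions = 10, n_samples = 120,
                                      separation = 0, seed = 7)
  tab_u <- select_k(un$vectors, k_range = 2:4, n_restarts = 5, seed = 3)
  expect_true(all(tab_u$silhouette < 0.2))

  tab1 <- select_k(fx$vectors, k_range = c(2, 2), n_restarts = 5, seed = 1)
  expect_identical(nrow(tab1), 2L)
})

test_that("occupancies are exact label fractions", {
  expect_equal(occupancy_probabilities(c(1, 1, 2, 3), 3), c(0.5, 0.25, 0.25))
  expect_equal(occupancy_probabilities(rep(2, 10), 3), c(0, 1, 0))
  expect_equal(sum(occupancy_probabilities(sample(1:4, 97, TRUE), 4)), 1)
  expect_error(occupancy_probabilities(integer(0), 3), "no labels")
  expect_error(occupancy_probabilities(c(1, 5), 3), "1..k")

  # long chain matches the stationary distribution of its TPM
  tpm <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  lab <- generate_markov_labels(tpm, 1e5, seed = 8)
  expect_lt(max(abs(occupancy_probabilities(lab, 2) - c(2 / 3, 1 / 3))), 0.02)
})

test_that("switching matrices count within-session transitions only", {
  sw <- switching_matrix(c(1, 2, 1, 2, 1), 3)
  expect_equal(sw[1, ], c(0, 1, 0))
  expect_equal(sw[2, ], c(1, 0, 0))
  expect_true(all(is.na(sw[3, ])))
  expect_identical(attr(sw, "unvisited"), 3L)

  const <- switching_matrix(rep(2, 5), 2)
  expect_equal(const[2, ], c(0, 1))

  # a boundary between sessions contributes no transition
  sw2 <- switching_matrix(list(c(1, 1), c(2, 2)), 2)
  expect_equal(sw2[1, 2], 0)
  expect_equal(sw2[2, 1], 0)

  expect_error(switching_matrix(1L, 2), "at least 2")
})

test_that("assignment to fixed centroids is nearest-neighbour with low-index ties", {
  cents <- diag(3)
  expect_identical(assign_to_centroids(diag(3), cents), c(1L, 2L, 3L))
  # exact tie between centroids 1 and 2: lowest index wins
  mid <- matrix(c(0.5, 0.5, 0), 1)
  expect_identical(assign_to_centroids(mid, cents), 1L)
  expect_error(assign_to_centroids(diag(3), cents[, 1:2]), "regions")

  # re-assigning the training eigenvectors reproduces clustering labels
  fx <- generate_eigenvector_clusters(3, 8, 90, separation = 6, seed = 9)
  cl <- cluster_states(fx$vectors, 3, n_restarts = 10, seed = 2)
  expect_identical(assign_to_centroids(fx$vectors, cl$centroids),
                   unlist(cl$labels, use.names = FALSE))
})

test_that("paired permutation test matches exhaustive sign-flip enumeration", {
  a <- c(5.1, 4.8, 5.5, 5.0, 4.9)
  expect_equal(permutation_paired_test(a, a, n_perm = 200, seed = 1)$p_value, 1)

  set.seed(10)
  b <- rnorm(10)
  a2 <- b + 2 + rnorm(10, sd = 0.5)
  res <- permutation_paired_test(a2, b, n_perm = 2000, seed = 2)
  expect_lte(res$p_value, 0.05)

  # exhaustive 2^10 enumeration oracle
  d <- a2 - b
  tval <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  tnull <- apply(signs, 1, function(s) tval(d * s))
  p_exact <- mean(abs(tnull) >= abs(tval(d)))
  expect_lt(abs(res$p_value - p_exact), 0.02)

  # two-sidedness: swapping the groups leaves p unchanged
  res_sw <- permutation_paired_test(b, a2, n_perm = 2000, seed = 2)
  expect_equal(res$p_value, res_sw$p_value)

  expect_error(permutation_paired_test(1, 1:2, 100, 1), "equal length")
  expect_error(permutation_paired_test(1, 2, 100, 1), "2 pairs")
})

test_that("the full chain recovers planted substate sequences from block signals", {
  n <- 8; tr <- 2; n_t <- 600
  patterns <- rbind(rep(1, n),
                    c(1, 1, 1, -1, -1, -1, -1, -1),
                    c(-1, -1, -1, -1, -1, 1, 1, 1))
  tpm <- matrix(0.0125, 3, 3); diag(tpm) <- 0.975
  lab <- generate_markov_labels(tpm, n_t, seed = 5)
  carrier <- cos(2 * pi * 0.05 * (0:(n_t - 1)) * tr)
  vals <- t(patterns[lab, ] * matrix(rep(carrier, n), n_t, n))
  set.seed(2)
  vals <- vals + 0.05 * matrix(rnorm(n * n_t), n, n_t)
  res <- run_leida(regional_ts(vals, tr_s = tr), k = 3, seed = 7)
  pred <- res$clustering$labels[[1]]
  true <- lab[4:(n_t - 3)]
  expect_gte(label_agreement(pred, true, 3), 0.95)
})
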