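small_record <- function(seed = 1, duration = 600, N = c(E = 20, I = 20, X = 20),
                         K = 5) {
  sp <- tiny_spec(N = N, K = K)
  real <- build_realization(sp, seed)
  cfg <- simulator_config(duration = duration * sp$tau, seed = seed + 100,
                          measurement_interval = sp$tau / 10)
  list(spec = sp, real = real,
       rec = simulate_network(real, cfg, record_states = TRUE))
}

test_that("a trace paired with itself recovers its variance; EI estimate is symmetric", {
  sr <- small_record()
  rec <- sr$rec
  pp <- getFromNamespace("per_pair_covariances", "binnet")
  self_pairs <- cbind(1:10, 1:10)
  cv <- pp(rec, self_pairs)$cov
  m <- rec$neuron_mean[1:10]
  expect_equal(cv, unname(m * (1 - m)), tolerance = 1e-12)

  ei <- cbind(1:10, 21:30)
  ie <- ei[, 2:1]
  expect_equal(pp(rec, ei)$cov, pp(rec, ie)$cov, tolerance = 1e-15)
})

test_that("variance estimator is consistent on independent binary sources", {
  # independent two-state processes: a -> m(1-m) with error O(1/sqrt(bins))
  sp <- tiny_spec(N = c(E = 1, I = 1, X = 100), K = 0)
  sp$m_X <- 0.25
  rec <- simulate_network(build_realization(sp, 1),
                          simulator_config(1600 * sp$tau, seed = 2,
                                           transient = 100 * sp$tau,
                                           measurement_interval = sp$tau),
                          record_states = TRUE, init = c(E = 0, I = 0))
  est <- suppressWarnings(pairwise_covariances(rec, n_pairs = 50))
  expect_lt(abs(est$variance[["X"]] - 0.25 * 0.75), 0.005)
  pp <- getFromNamespace("per_pair_covariances", "binnet")
  xx <- pp(rec, cbind(2 + seq(1, 99, 2), 2 + seq(2, 100, 2)))$cov
  expect_lt(abs(mean(xx)), 3 * stats::sd(xx) / sqrt(length(xx)))
})

test_that("streaming pair accumulators agree with the stored-states path", {
  sp <- tiny_spec(N = c(E = 40, I = 40, X = 30), K = 8)
  real <- build_realization(sp, 3)
  pairs <- sample_pairs(sp, 15, seed = 5)
  cfg <- simulator_config(400 * sp$tau, seed = 7, measurement_interval = sp$tau / 5)
  rec_both <- simulate_network(real, cfg, record_states = TRUE, pairs = pairs)
  est_stream <- pairwise_covariances(rec_both)
  rec_states <- simulate_network(real, cfg, record_states = TRUE)
  pp <- getFromNamespace("per_pair_covariances", "binnet")
  cv_states <- pp(rec_states, pairs)$cov
  expect_equal(unname(est_stream$per_pair$cov), unname(cv_states),
               tolerance = 1e-12)
})

test_that("input-covariance decomposition is exact and classifies correctly", {
  sr <- small_record(seed = 4, duration = 300)
  pairs <- cbind(c(1L, 3L, 21L), c(2L, 4L, 22L))
  dec <- input_correlation_components_empirical(sr$rec, sr$real, pairs)
  expect_lt(dec$max_residual, 1e-10)

  # identical afferent sets: the measured total equals the input variance,
  # and with independent (external) afferents the shared part carries it
  real2 <- sr$real
  i <- 1L; j <- 2L
  idx_i <- seq.int(real2$ptr[i] + 1L, real2$ptr[i + 1L])
  idx_j <- seq.int(real2$ptr[j] + 1L, real2$ptr[j + 1L])
  expect_equal(length(idx_i), length(idx_j))
  real2$src[idx_j] <- real2$src[idx_i]
  real2$w[idx_j] <- real2$w[idx_i]
  dec2 <- input_correlation_components_empirical(sr$rec, real2, cbind(i, j))
  h <- getFromNamespace("neuron_input_trace", "binnet")(sr$rec, real2, i)$total
  expect_equal(unname(dec2$per_pair[1, "total"]), mean(h^2) - mean(h)^2,
               tolerance = 1e-12)
  expect_lt(dec2$max_residual, 1e-10)
})

test_that("feedforward-only pairs have zero correlation component in expectation", {
  # local weights zeroed, shared external kept: afferents are independent
  sp <- tiny_spec(N = c(E = 30, I = 30, X = 15), K = 0)
  sp$K[, "X"] <- 10L
  sp$J[, "X"] <- 0.2
  sp <- rebalance_threshold(sp, 0.3)
  real <- build_realization(sp, 6)
  rec <- simulate_network(real, simulator_config(1500 * sp$tau, seed = 8,
                                                 measurement_interval = sp$tau / 5),
                          record_states = TRUE)
  pairs <- cbind(seq(1, 29, 2), seq(2, 30, 2))
  dec <- input_correlation_components_empirical(rec, real, pairs)
  # afferents are independent sources: the correlation component is only
  # sampling noise, a small fraction of the shared component
  expect_lt(abs(dec$corr), 0.1 * dec$shared)
  expect_gt(dec$shared, 0)
})

test_that("population-average identity is exact under exhaustive enumeration", {
  sr <- small_record(seed = 9, duration = 200)
  for (pop in c("E", "I")) {
    chk <- population_average_identity_check(sr$rec, pop)
    expect_lt(abs(chk$residual), 1e-14)
  }
  # subsampled pairs: residual within the pair-sampling error
  pairs <- sample_pairs(sr$spec, 10, seed = 2, labels = "EE")
  chk_sub <- population_average_identity_check(sr$rec, "E", pairs = pairs)
  pp <- getFromNamespace("per_pair_covariances", "binnet")
  cv <- pp(sr$rec, pairs)$cov
  se <- stats::sd(cv) / sqrt(length(cv))
  expect_lt(abs(chk_sub$residual), 4 * se)
})

test_that("population average of iid sources has variance a/N", {
  sp <- tiny_spec(N = c(E = 1, I = 1, X = 50), K = 0)
  sp$m_X <- 0.3
  rec <- simulate_network(build_realization(sp, 2),
                          simulator_config(2100 * sp$tau, seed = 3,
                                           transient = 100 * sp$tau,
                                           measurement_interval = sp$tau),
                          record_states = TRUE, init = c(E = 0, I = 0))
  chk <- population_average_identity_check(rec, "X")
  expect_lt(abs(chk$residual), 1e-14)        # identity is algebraic
  expect_lt(abs(chk$c_bar) * (chk$n - 1), chk$a_bar)  # pair term subdominant
  expect_lt(abs(chk$lhs - chk$a_bar / 50), 3 * chk$a_bar / 50 / sqrt(1000))
})

test_that("pair sampling is disjoint, label-complete and clamps gracefully", {
  sp <- tiny_spec(N = c(E = 20, I = 20, X = 6), K = 3)
  w <- capture_warnings(p <- sample_pairs(sp, 10, seed = 1))
  expect_match(w, "only 6", all = TRUE)
  expect_length(w, 2)  # EX and IX both clamp
  lab <- attr(p, "label")
  expect_setequal(unique(lab), c("EE", "EI", "II", "EX", "IX"))
  for (lb in c("EE", "EI", "II")) {
    sub <- p[lab == lb, , drop = FALSE]
    expect_false(anyDuplicated(as.vector(sub)) > 0)
  }
  expect_equal(sum(lab == "EX"), 6)
  spdc <- sp; spdc$external_mode <- "dc"
  pdc <- sample_pairs(spdc, 5, seed = 1)
  expect_setequal(unique(attr(pdc, "label")), c("EE", "EI", "II"))
})
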