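test_that("effective couplings are S*K*J and vanish with S", {
  sp <- fixture_spec("homogeneous_small")
  mf <- solve_mean_field(sp)
  eff <- effective_couplings(sp, mf)
  expect_equal(eff$w["I", "I"], unname(mf$S["I"] * sp$K["I", "I"] * sp$J["I", "I"]))
  mf0 <- mf; mf0$S[] <- 0
  expect_true(all(effective_couplings(sp, mf0)$w == 0))
  mf1 <- mf; mf1$S[] <- c(0.5, 0.5)
  expect_equal(effective_couplings(sp, mf1)$w["E", "I"],
               unname(0.5 * sp$K["E", "I"] * sp$J["E", "I"]))
})

test_that("effective coupling matches the simulated response to a rate perturbation", {
  sp <- fixture_spec("homogeneous_small")
  it <- iterate_self_consistent(sp)
  # bump the external rate and compare the activity shift with the linear
  # prediction dm = (1 - W_L)^{-1} w_X dm_X
  dmx <- 0.02
  sp2 <- sp; sp2$m_X <- sp$m_X + dmx
  run <- function(s, seed) {
    real <- build_realization(s, 31)
    rec <- simulate_network(real, simulator_config(2100 * s$tau, seed = seed,
                                                   transient = 100 * s$tau,
                                                   measurement_interval = s$tau / 5),
                            init = it$mf$m)
    activity_means(rec)[c("E", "I")]
  }
  d_emp <- rowMeans(sapply(1:3, function(k) run(sp2, 40 + k) - run(sp, 40 + k)))
  eff <- effective_couplings(sp, it$mf)
  d_lin <- solve(diag(2) - eff$w[, c("E", "I")], eff$w[, "X"]) * dmx
  expect_lt(max(abs(d_emp - d_lin)), 0.35 * max(abs(d_lin)) + 0.002)
})

test_that("block solves agree with the independently assembled dense 5x5 system", {
  for (nm in c("three_population", "homogeneous_small", "inhomogeneous",
               "purely_inhibitory", "structural_base")) {
    sp <- fixture_spec(nm)
    mf <- solve_mean_field(sp)
    cs <- solve_correlations(sp, mf)
    oracle <- dense_covariance_oracle(sp, mf)
    expect_rel_equal(covariance_vector(cs), oracle, 1e-12)
  }
})

test_that("external covariances are independent of the local ones and of dc sources", {
  sp <- fixture_spec("homogeneous_small")
  mf <- solve_mean_field(sp)
  eff <- effective_couplings(sp, mf)
  a_x <- sp$m_X * (1 - sp$m_X)
  cx <- solve_external_block(eff, a_x, sp$N["X"])
  # hand solve of the 2x2 system
  M <- 2 * diag(2) - eff$w[, c("E", "I")]
  expect_equal(unname(cx), unname(solve(M, eff$w[, "X"] * a_x / sp$N["X"])),
               tolerance = 1e-14)
  expect_equal(unname(solve_external_block(eff, 0, sp$N["X"])),
               c(0, 0))  # dc mode: no source, no covariance
  # homogeneous rows give c_EX = c_IX
  expect_equal(unname(cx["c_EX"]), unname(cx["c_IX"]), tolerance = 1e-13)
})

test_that("feedforward external block reduces to the open-loop value", {
  sp <- tiny_spec(N = c(E = 200, I = 200, X = 100), K = 0)
  sp$K[, "X"] <- 30L; sp$J[, "X"] <- 0.15
  sp <- rebalance_threshold(sp, 0.3)
  mf <- solve_mean_field(sp)
  eff <- effective_couplings(sp, mf)
  a_x <- sp$m_X * (1 - sp$m_X)
  cx <- solve_external_block(eff, a_x, sp$N["X"])
  expect_equal(unname(cx), unname(eff$w[, "X"] * a_x / sp$N["X"] / 2),
               tolerance = 1e-14)
})

test_that("solutions are linear in the sources and the blocks superpose", {
  sp <- fixture_spec("inhomogeneous")
  mf <- solve_mean_field(sp)
  full <- covariance_vector(solve_correlations(sp, mf))
  ext <- covariance_vector(solve_correlations(sp, mf, sources = "external"))
  int <- covariance_vector(solve_correlations(sp, mf, sources = "intrinsic"))
  expect_equal(ext + int, full, tolerance = 1e-14)
  # scaling all variances by kappa scales all covariances by kappa
  oracle1 <- dense_covariance_oracle(sp, mf)
  oracle2 <- dense_covariance_oracle(sp, mf,
    a_override = c(E = 3 * mf$a[["E"]], I = 3 * mf$a[["I"]],
                   X = 3 * sp$m_X * (1 - sp$m_X)))
  expect_rel_equal(oracle2, 3 * oracle1, 1e-12)
})

test_that("singular working points are refused with the eigenvalue named", {
  w <- matrix(c(2, 0, 0, 0, 0.5, 0.5), 2, 3,
              dimnames = list(c("E", "I"), c("E", "I", "X")))
  expect_error(solve_external_block(w, 0.1, 100), "singular")
})

test_that("purely inhibitory network collapses to the scalar closed form", {
  sp <- fixture_spec("purely_inhibitory")
  mf <- solve_mean_field(sp)
  cs <- solve_correlations(sp, mf)
  w <- effective_couplings(sp, mf)$w["I", "I"]
  closed <- inhibitory_covariance(w, mf$a[["I"]], sp$N[["I"]])
  expect_lt(abs(cs$c_II - closed) / abs(closed), 1e-12)
  expect_lt(cs$c_II, 0)
  # strong-feedback limit: c -> -a/N
  expect_equal(inhibitory_covariance(-1e12, 0.16, 1000), -0.16 / 1000,
               tolerance = 1e-9)
})

test_that("N_X only shifts the covariances; the splitting is invariant", {
  diffs <- sapply(c(100, 400, 1600), function(nx) {
    sp <- fixture_spec("three_population", N_X = nx)
    mf <- solve_mean_field(sp)
    cs <- solve_correlations(sp, mf)
    c(d1 = cs$c_EE - cs$c_EI, d2 = cs$c_EI - cs$c_II, off = cs$c_EI)
  })
  expect_lt(max(abs(diffs["d1", ] - diffs["d1", 1])), 1e-10)
  expect_lt(max(abs(diffs["d2", ] - diffs["d2", 1])), 1e-10)
  # the common offset does change (smaller external pool -> larger offset)
  expect_true(all(diff(diffs["off", ]) < 0))
  # homogeneous connectivity: equidistant structure
  expect_equal(unname(diffs["d1", 1]), unname(diffs["d2", 1]), tolerance = 1e-14)
})

test_that("iteration converges to a reproducing fixed point", {
  sp <- fixture_spec("homogeneous_small")
  it <- iterate_self_consistent(sp, tolerance = 1e-10)
  expect_true(it$converged)
  # one more sweep reproduces the fixed point
  mf2 <- solve_mean_field(sp, cs = it$cs, start = it$mf$m)
  cs2 <- solve_correlations(sp, mf2)
  expect_lt(max(abs(covariance_vector(cs2) - covariance_vector(it$cs))), 1e-9)
  expect_lt(max(abs(mf2$m - it$mf$m)), 1e-9)
})

test_that("without connections the iteration ends at the plain mean field", {
  sp <- tiny_spec(N = c(E = 50, I = 50, X = 100), K = 0)
  sp$theta <- c(E = 0.8, I = 0.8)   # no inputs at all: deterministic silence
  it <- iterate_self_consistent(sp)
  expect_true(it$converged)
  expect_lte(it$iterations, 2)
  mf <- solve_mean_field(sp)
  expect_equal(it$mf$m, mf$m, tolerance = 1e-10)
  expect_equal(unname(it$mf$m), c(0, 0))
  expect_equal(it$cs$c_EE, 0, tolerance = 1e-15)
})

test_that("Cauchy-Schwarz bound holds on all canonical fixtures", {
  for (nm in fixture_names()) {
    sp <- fixture_spec(nm)
    mf <- solve_mean_field(sp)
    cs <- solve_correlations(sp, mf)
    a <- cs$a
    bound <- c(EE = unname(a["E"]), EI = unname(sqrt(a["E"] * a["I"])),
               II = unname(a["I"]),
               EX = unname(sqrt(a["E"] * max(a["X"], 1e-300))),
               IX = unname(sqrt(a["I"] * max(a["X"], 1e-300))))
    v <- covariance_vector(cs)
    expect_true(all(abs(v[c("EE", "EI", "II")]) <=
                      bound[c("EE", "EI", "II")]), info = nm)
  }
})

test_that("theoretical input-correlation decomposition is exact and cancels", {
  sp <- fixture_spec("three_population", N_X = 400)
  it <- iterate_self_consistent(sp)
  for (tg in c("E", "I")) {
    q <- input_correlation_theory(sp, it$mf, it$cs, tg)
    expect_lt(abs(q$identity_residual) / abs(q$popavg_variance), 1e-12)
    expect_gt(q$shared[["total"]], 0)
    expect_lt(q$corr[["total"]], 0)
    expect_lt(abs(q$total), 0.25 * min(abs(q$shared[["total"]]),
                                       abs(q$corr[["total"]])))
  }
  # feedforward control: no local weights, no correlation component
  sp0 <- tiny_spec(N = c(E = 200, I = 200, X = 100), K = 0)
  sp0$K[, "X"] <- 30L; sp0$J[, "X"] <- 0.15
  sp0 <- rebalance_threshold(sp0, 0.3)
  mf0 <- solve_mean_field(sp0)
  cs0 <- solve_correlations(sp0, mf0)
  q0 <- input_correlation_theory(sp0, mf0, cs0, "E")
  expect_equal(q0$corr[["local"]], 0)
  expect_equal(q0$total, q0$shared[["external"]] + q0$corr[["external"]],
               tolerance = 1e-15)
})

test_that("inhibitory cancellation ratio approaches -1 monotonically with coupling", {
  ratios <- sapply(c(25, 100, 400, 1600), function(K) {
    sp <- fixture_spec("purely_inhibitory")
    sp$N["I"] <- 4000; sp$K["I", "I"] <- K
    sp <- local({  # rebalance for the inhibitory population alone
      m <- c(E = 0, I = 0.2)
      sp$theta["I"] <- mean_input(sp, m)["I"] -
        sqrt(input_variance(sp, m)["I"]) * stats::qnorm(0.2)
      sp
    })
    mf <- solve_mean_field(sp)
    q <- input_correlation_theory(sp, mf, solve_correlations(sp, mf), "I")
    c(ratio = q$corr[["total"]] / q$shared[["total"]], total = q$total)
  })
  expect_true(all(diff(ratios["ratio", ]) < 0))
  expect_true(all(ratios["ratio", ] > -1))
  expect_gt(ratios["ratio", 4], -1)
  expect_lt(ratios["ratio", 4], -0.9)
  expect_true(all(ratios["total", ] > 0))
})
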