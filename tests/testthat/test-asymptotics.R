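test_that("closed-form spectrum matches a dense eigenvalue routine", {
  set.seed(4)
  for (k in 1:50) {
    w <- matrix(stats::rnorm(4, sd = 3), 2, 2,
                dimnames = list(c("E", "I"), c("E", "I")))
    sm <- spectrum(w)
    ev <- eigen(w, only.values = TRUE)$values
    expect_lt(max(abs(sort(Re(sm$eigenvalues)) - sort(Re(ev)))), 1e-12)
    expect_lt(max(abs(sort(abs(Im(as.complex(sm$eigenvalues)))) -
                        sort(abs(Im(as.complex(ev)))))), 1e-12)
  }
})

test_that("degenerate rows give an exactly zero eigenvalue; pure cross-coupling oscillates", {
  sp <- fixture_spec("three_population")
  mf <- solve_mean_field(sp)
  sm <- spectrum(effective_couplings(sp, mf))
  expect_identical(sm$det, 0)
  expect_true(any(sm$eigenvalues == 0))
  expect_true(sm$degenerate)
  # both self-couplings zero, E<->I only: conjugate complex pair
  w <- matrix(c(0, 2, -8, 0), 2, 2, byrow = TRUE)
  sm2 <- spectrum(w)
  expect_true(sm2$oscillatory)
  expect_equal(sm2$eigenvalues[1], Conj(sm2$eigenvalues[2]))
})

test_that("external and intrinsic contributions sum exactly to the full solution", {
  for (nm in c("inhomogeneous", "three_population", "purely_inhibitory")) {
    sp <- fixture_spec(nm)
    for (st in c("external", "intrinsic")) {
      dec <- decompose_contributions(sp, self_term = st)
      expect_lt(dec$residual, 1e-16 + 1e-10 * max(abs(dec$full)))
    }
  }
})

test_that("dc mode: all external source terms vanish", {
  sp <- fixture_spec("inhomogeneous", external_mode = "dc")
  # under the intrinsic attribution of the single-cell term, the external
  # part vanishes identically without an external variance source
  dec <- decompose_contributions(sp, self_term = "intrinsic")
  expect_equal(unname(dec$external), rep(0, 5))
  expect_equal(dec$intrinsic, dec$full)
  # under the default attribution only the single-cell self term remains
  dec2 <- decompose_contributions(sp, self_term = "external")
  expect_equal(unname(dec2$external[c("EI", "EX", "IX")]), rep(0, 3))
})

test_that("hypothetical silent local populations generate no intrinsic covariance", {
  sp <- fixture_spec("inhomogeneous")
  mf <- solve_mean_field(sp)
  mf0 <- mf; mf0$a <- c(E = 0, I = 0)
  cs_int <- solve_correlations(sp, mf0, sources = "intrinsic")
  expect_equal(unname(covariance_vector(cs_int)), rep(0, 5))
})

test_that("intrinsic contribution decays faster than 1/N for invertible coupling", {
  base <- scale_spec(fixture_spec("inhomogeneous"), 512 / 2000, m_target = 0.2)
  lad <- n_ladder(base, factors = 2^(0:5), m_target = 0.2)
  tab <- lad$table
  # pooled magnitude of the intrinsic part, rescaled by N: must decay
  int_norm <- vapply(split(tab, tab$factor), function(d)
    sqrt(sum(d$intrinsic[d$label %in% c("EE", "EI", "II")]^2)), numeric(1))
  N <- vapply(split(tab, tab$factor), function(d) d$N[1], numeric(1))
  o <- order(N)
  expect_true(all(diff((int_norm * N)[o]) < 0))
  # and faster than 1/N overall: fitted slope below -1
  expect_lt(unname(coef(lm(log(int_norm[o]) ~ log(N[o])))[2]), -1.05)
  # the external part carries the leading 1/N behaviour: N * c^ext stays
  # within a bounded band while N * c^int collapses
  ext_norm <- vapply(split(tab, tab$factor), function(d)
    sqrt(sum(d$external[d$label %in% c("EE", "EI", "II")]^2)), numeric(1))
  ratio <- (ext_norm * N)[o] / (ext_norm * N)[o][1]
  expect_true(all(ratio > 0.3 & ratio < 3))
})

test_that("invertible limit formula: full solution converges to it on the ladder", {
  base <- scale_spec(fixture_spec("inhomogeneous"), 512 / 2000, m_target = 0.2)
  dev <- sapply(2^(2:6), function(f) {
    sp <- scale_spec(base, f, m_target = 0.2)
    mf <- solve_mean_field(sp)
    full <- covariance_vector(solve_correlations(sp, mf))
    lim <- limit_inhomogeneous(sp, mf)
    sqrt(sum((full - lim)^2) / sum(lim^2))
  })
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[length(dev)], 0.5)
  # homogeneous connectivity is refused with the zero eigenvalue named
  expect_error(limit_inhomogeneous(fixture_spec("three_population")),
               "singular")
})

test_that("homogeneous limit: 1/N scaling, susceptibility-free, ladder agreement", {
  base <- scale_spec(fixture_spec("three_population", N_X = 400), 1 / 4,
                     m_target = 0.2)
  lim1 <- limit_homogeneous(base)
  sp2 <- scale_spec(base, 2, m_target = 0.2)
  lim2 <- limit_homogeneous(sp2)
  # doubling all sizes at fixed connection probability halves every entry
  expect_rel_equal(lim2, lim1 / 2, 1e-10)
  # external + intrinsic parts reproduce the total
  expect_equal(attr(lim1, "external") + attr(lim1, "intrinsic"),
               c(lim1), tolerance = 1e-14)
  # agreement with the full solver improves along the ladder
  dev <- sapply(2^(0:5), function(f) {
    sp <- scale_spec(base, f, m_target = 0.2)
    mf <- solve_mean_field(sp)
    full <- covariance_vector(solve_correlations(sp, mf))
    lim <- limit_homogeneous(sp, mf)
    sqrt(sum((full - lim)^2) / sum(lim^2))
  })
  expect_true(all(diff(dev) < 0))
  expect_error(limit_homogeneous(fixture_spec("inhomogeneous")),
               "not homogeneous")
})

test_that("fast-tracking prediction cancels input correlations exactly yet differs from finite N", {
  sp <- fixture_spec("three_population", N_X = 400)
  it <- iterate_self_consistent(sp)
  ft <- fast_tracking_prediction(sp, it$mf)
  cs_ft <- it$cs
  cs_ft$c_EE <- ft[["EE"]]; cs_ft$c_EI <- ft[["EI"]]; cs_ft$c_II <- ft[["II"]]
  cs_ft$c_EX <- ft[["EX"]]; cs_ft$c_IX <- ft[["IX"]]
  for (tg in c("E", "I")) {
    q <- input_correlation_theory(sp, it$mf, cs_ft, tg)
    # perfect tracking <=> zero variance of the population-averaged input
    expect_lt(abs(q$popavg_variance), 1e-15 * abs(q$shared[["total"]]))
    expect_lt(abs(q$total), 1e-15 * abs(q$shared[["total"]]))
  }
  full <- covariance_vector(it$cs)
  expect_gt(max(abs(ft - full)), 0.5 * max(abs(full)))
  expect_error(fast_tracking_prediction(fixture_spec("inhomogeneous")),
               "homogeneous")
})

test_that("shift sweep translates eigenvalues rigidly; split sweep turns them complex", {
  sp <- fixture_spec("structural_base")
  sw <- structural_sweep(sp, "shift", n_points = 5)
  sep <- sw$re_nu1 - sw$re_nu2
  expect_lt(max(abs(sep - sep[1])), 1e-10)
  expect_true(all(diff(sw$re_nu1) > 0))
  expect_true(all(diff(sw$re_nu2) > 0))

  sw2 <- structural_sweep(sp, "split", n_points = 9)
  expect_true(any(sw2$nu_split < 0) && any(sw2$nu_split > 0))
  # predicted merge point: discriminant zero of the structural matrix
  kE <- 20; kI <- -80
  t_star <- 2 * sqrt(-kE * kI) / abs(kE - kI)
  sw_star <- structural_sweep(sp, "split", grid = t_star)
  expect_lt(abs(sw_star$nu_split), 1e-8 * kE^2)
  # covariance magnitude is maximal at the degenerate-row endpoint
  for (s in list(sw, sw2)) {
    mags <- apply(abs(s[, c("c_EE", "c_EI", "c_II")]), 1, max)
    expect_equal(which.max(mags), nrow(s))
  }
})

test_that("fixed-K ladder leaves the effective couplings unchanged", {
  sp <- fixture_spec("homogeneous_small")
  sp2 <- scale_spec(sp, 4, mode = "fixed_K", m_target = 0.2)
  expect_equal(sp2$K, sp$K)
  expect_equal(unname(sp2$N), unname(sp$N * 4))
  mf1 <- solve_mean_field(rebalance_threshold(sp, 0.2))
  mf2 <- solve_mean_field(sp2)
  expect_equal(effective_couplings(sp, mf1)$w,
               effective_couplings(sp2, mf2)$w, tolerance = 1e-8)
})
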