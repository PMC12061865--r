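test_that("transfer function equals the analytic limit 1/d at threshold and is continuous there", {
  # excitatory and inhibitory parameter sets of both regions
  expect_equal(transfer_rate(0.4, 310, 0.16, 0.4), 1 / 0.16, tolerance = 1e-12)
  expect_equal(transfer_rate(0.286, 615, 0.087, 0.286), 1 / 0.087,
               tolerance = 1e-12)

  # approaching the threshold from both sides converges to 1/d
  for (eps in 10^-(6:9)) {
    expect_equal(transfer_rate(0.4 + eps, 310, 0.16, 0.4), 6.25,
                 tolerance = 310 * 0.16 * eps)
    expect_equal(transfer_rate(0.4 - eps, 310, 0.16, 0.4), 6.25,
                 tolerance = 310 * 0.16 * eps)
  }
  # no jump across the series/formula branch boundary (|d*g*x| = 1e-6)
  x_at <- 1e-6 / (0.16 * 310)
  lo <- transfer_rate(0.4 + 0.99 * x_at, 310, 0.16, 0.4)
  hi <- transfer_rate(0.4 + 1.01 * x_at, 310, 0.16, 0.4)
  expect_lt(abs(hi - lo) / lo, 1e-5)
})

test_that("transfer function matches direct evaluation and is strictly increasing and nonnegative", {
  # frozen high-precision evaluation of g*(I-thr)/(1-exp(-d*g*(I-thr)))
  expect_equal(transfer_rate(0.42, 310, 0.16, 0.4), 9.854319468,
               tolerance = 1e-9)
  grid <- seq(0.0, 0.8, by = 0.005)
  r <- transfer_rate(grid, 310, 0.16, 0.4)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0))
  r2 <- transfer_rate(grid, 615, 0.087, 0.286)
  expect_true(all(diff(r2) > 0))
  expect_error(transfer_rate(NaN, 310, 0.16, 0.4), "non-finite")
  expect_error(transfer_rate(Inf, 310, 0.16, 0.4), "non-finite")
  expect_error(transfer_rate(0.4, -310, 0.16, 0.4), "positive")
})

test_that("inflammation factors reproduce closed-form values and the Heaviside gate", {
  kin <- kinetics_params(c1 = 5, m = 2, c2 = 0.019)
  # control: gate closed regardless of B
  for (B in c(1, 0.55, 0.1)) {
    f <- inflammation_factors(inflammation_condition(degree = 1, B = B), kin)
    expect_identical(unname(f), c(1, 1))
  }
  # gate closed below control too
  f <- inflammation_factors(inflammation_condition(degree = 0.8), kin)
  expect_identical(unname(f), c(1, 1))
  # severe, untreated: X1 = 25/(25 + 5.29), X2 = 1 + 0.019*2.3
  f <- inflammation_factors(inflammation_condition(degree = 2.3, B = 1), kin)
  expect_equal(unname(f), c(25 / 30.29, 1.0437), tolerance = 1e-12)
  expect_equal(unname(f), c(0.8253549, 1.0437), tolerance = 1e-6)
  # severe with blocker
  f <- inflammation_factors(inflammation_condition(degree = 2.3, B = 0.55),
                            kin)
  expect_equal(unname(f), c(0.8957523, 1.024035), tolerance = 1e-6)
})

test_that("X1 decreases and X2 increases with degree; blocker moves both toward one", {
  kin <- kinetics_params(c1 = 5, m = 2, c2 = 0.019)
  degs <- seq(1.01, 4, length.out = 40)
  fac <- vapply(degs, function(d)
    inflammation_factors(inflammation_condition(degree = d), kin), numeric(2))
  expect_true(all(diff(fac[1, ]) < 0))
  expect_true(all(diff(fac[2, ]) > 0))
  expect_true(all(fac[1, ] > 0 & fac[1, ] <= 1))
  expect_true(all(fac[2, ] >= 1))
  # lowering B attenuates the cytokine term: X1 rises toward 1, X2 falls
  # toward 1, i.e. dX1/dB <= 0 by finite differences
  for (d in c(1.25, 1.4, 2.3)) {
    h <- 1e-6
    x1 <- function(B)
      inflammation_factors(inflammation_condition(degree = d, B = B),
                           kin)[["X1"]]
    expect_lte((x1(0.7 + h) - x1(0.7 - h)) / (2 * h), 0)
    f_blocked <- inflammation_factors(
      inflammation_condition(degree = d, B = 0.55), kin)
    f_plain <- inflammation_factors(inflammation_condition(degree = d), kin)
    expect_gt(f_blocked[["X1"]], f_plain[["X1"]])
    expect_lt(f_blocked[["X2"]], f_plain[["X2"]])
  }
  expect_error(inflammation_condition(degree = -0.5), "degree")
  expect_error(inflammation_condition(degree = 2, B = 0), "B")
  expect_error(inflammation_condition(degree = 2, B = 1.5), "B")
})

test_that("regional currents match direct arithmetic, including the SCC minus sign", {
  pfc <- region_params("PFC")
  scc <- region_params("SCC")
  # frozen direct arithmetic on the published parameter values
  cur <- region_currents(0.2, 0.1, 0.6, pfc, 0.2)
  expect_equal(cur[["I_E"]], 0.4216, tolerance = 1e-12)
  cur <- region_currents(0.2, 0.1, 0.6, scc, 0.2)
  expect_equal(cur[["I_E"]], 0.36083, tolerance = 1e-12)
  # zero state and zero external input give zero currents
  p0 <- region_params("PFC", Io = 0)
  expect_equal(unname(region_currents(0, 0, 0, p0, 0)), c(0, 0))
})

test_that("currents are affine: superposition holds on the state-dependent part", {
  set.seed(1)
  for (reg in c("PFC", "SCC")) {
    p <- region_params(reg)
    base <- region_currents(0, 0, 0, p, 0)
    lin <- function(s) region_currents(s[1], s[2], s[3], p, s[4]) - base
    for (i in 1:10) {
      s1 <- stats::runif(4); s2 <- stats::runif(4)
      a <- stats::rnorm(1); b <- stats::rnorm(1)
      expect_equal(lin(a * s1 + b * s2), a * lin(s1) + b * lin(s2),
                   tolerance = 1e-10)
    }
  }
})

test_that("serotonergic input excites PFC and inhibits SCC", {
  pfc <- region_params("PFC")
  scc <- region_params("SCC")
  Ms <- seq(0, 1, by = 0.1)
  ie_pfc <- vapply(Ms, function(M)
    region_currents(0.2, 0.1, M, pfc, 0.2)[["I_E"]], numeric(1))
  ie_scc <- vapply(Ms, function(M)
    region_currents(0.2, 0.1, M, scc, 0.2)[["I_E"]], numeric(1))
  expect_true(all(diff(ie_pfc) > 0))
  expect_true(all(diff(ie_scc) < 0))
})

test_that("gating drift has the closed-form fixed points", {
  p <- region_params("PFC")
  # growth term vanishes at S_E = 1
  gd <- gating_derivatives(1, 0.1, 37, 5, p)
  expect_equal(gd[["dS_E"]], -1 / p$tau_NMDA, tolerance = 1e-12)
  # S_I* = tau_GABA * r_I
  gd <- gating_derivatives(0.2, 0.04, 4.61, 4, p)
  expect_equal(gd[["dS_I"]], 0, tolerance = 1e-12)
  # S_E* = gamma*tau*r / (1 + gamma*tau*r), frozen at r = 4.61 Hz
  se_star <- 0.2280978556
  gd <- gating_derivatives(se_star, 0.04, 4.61, 4, p)
  expect_equal(gd[["dS_E"]], 0, tolerance = 1e-9)
  expect_error(gating_derivatives(0.2, 0.04, -1, 4, p), "nonnegative")
})

test_that("serotonergic current equilibrium follows the concentration sigmoid", {
  kin <- kinetics_params()
  m_star <- function(conc)
    stats::uniroot(function(M) serotonergic_current_derivative(M, conc, kin),
                   c(0, 1), tol = 1e-12)$root
  # frozen sigmoid evaluations: 1/(1+exp(-0.008*(conc+1)))
  expect_equal(m_star(66.35), 0.6315332, tolerance = 1e-6)
  expect_equal(m_star(0), 0.5020000, tolerance = 1e-6)
  # saturation toward J_5HT
  expect_equal(m_star(1e6), kin$J_5HT, tolerance = 1e-3)
  # equilibrium increases with concentration and stays in (0, J_5HT)
  eq <- vapply(seq(0, 200, by = 20), m_star, numeric(1))
  expect_true(all(diff(eq) > 0))
  expect_true(all(eq > 0 & eq < kin$J_5HT))
  expect_error(serotonergic_current_derivative(0.5, -1, kin), "nonnegative")
})

test_that("serotonin drift: synthesis-only at zero concentration, half-maximal reuptake at Km", {
  kin <- kinetics_params()
  expect_equal(serotonin_derivative(4.61, 0, 1, 1, kin),
               kin$alpha * kin$C_BR * 4.61, tolerance = 1e-12)
  # at conc = Km the reuptake term is Vmax/2 = 650 nM/s
  expect_equal(serotonin_derivative(0, kin$Km, 1, 1, kin), -650,
               tolerance = 1e-12)
  expect_error(serotonin_derivative(4, -1, 1, 1, kin), "nonnegative")
})

test_that("closed-form serotonin fixed point agrees with an independent root-finder", {
  kin <- kinetics_params()
  # frozen closed form at the control rate: Km*s/(1-s), s = alpha*C_BR*r/Vmax
  expect_equal(serotonin_fixed_point(4.61, 1, 1, kin), 61.59549384,
               tolerance = 1e-7)
  cases <- expand.grid(r = c(2.5, 3.79, 4.61, 5.2),
                       X1 = c(1, 0.8253549), X2 = c(1, 1.0437))
  for (i in seq_len(nrow(cases))) {
    cc <- cases[i, ]
    root <- stats::uniroot(
      function(conc) serotonin_derivative(cc$r, conc, cc$X1, cc$X2, kin),
      c(0, 5000), tol = 1e-10)$root
    expect_equal(serotonin_fixed_point(cc$r, cc$X1, cc$X2, kin), root,
                 tolerance = 1e-8)
  }
  # synthesis beyond maximal reuptake has no fixed point
  expect_error(serotonin_fixed_point(20, 1, 1, kin), "u >= 1")
})

test_that("parameter constructors validate their invariants", {
  expect_error(region_params("PFC", tau_NMDA = -0.1), "positive")
  expect_error(region_params("PFC", g_E = 0), "positive")
  expect_error(kinetics_params(Vmax = -5), "positive")
  p <- region_params("PFC")
  expect_identical(p$serotonergic_sign, 1)
  expect_identical(region_params("SCC")$serotonergic_sign, -1)
  # defaults reproduce the published table values
  expect_identical(c(p$I_thr_E, p$g_E, p$d_E, p$J_NMDA, p$Io, p$W_I),
                   c(0.4, 310, 0.16, 0.15, 0.32, 0.7))
  s <- region_params("SCC")
  expect_identical(c(s$J_NMDA, s$Io, s$W_I, s$W5HT_E, s$C_in),
                   c(0.33, 0.45, 0.8, 0.19, 0.005))
  k <- kinetics_params()
  expect_identical(c(k$alpha, k$C_BR, k$Vmax, k$Km, k$tau_5HT, k$beta),
                   c(5, 15, 1300, 170, 0.12, 0.008))
  mp <- default_params()
  expect_identical(mp$kinetics$pfc$c1, 5)
  expect_identical(mp$kinetics$scc$c1, 4)
})
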