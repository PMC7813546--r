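# Reaction-diffusion steady state: profiles, linear solver vs closed form
# and lattice oracle, nonlinear solver, speed/fidelity extraction.

test_that("substrate profiles are normalized and shaped as documented", {
  g <- rd_grid(10, 100)
  uni <- substrate_profile(g, "uniform", Ntot = 100)
  expect_equal(uni$rho, rep(10, 100))
  expo <- substrate_profile(g, "exponential", lambdaS = 10, Ntot = 3)
  expect_equal(sum(expo$rho) * g$dx, 3, tolerance = 1e-12)
  # one decay length across the box: rho(0)/rho(L) = e
  expect_equal(expo$rho[1] / expo$rho[100], exp((g$x[100] - g$x[1]) / 10),
               tolerance = 1e-12)
  del <- substrate_profile(g, "delta", Ntot = 1)
  expect_equal(del$rho[1], 1 / g$dx)
  expect_true(all(del$rho[-1] == 0))
  # lambdaS edge cases degrade to delta / uniform
  expect_identical(substrate_profile(g, "exponential", lambdaS = 0)$kind,
                   "delta")
  expect_identical(substrate_profile(g, "exponential", lambdaS = Inf)$kind,
                   "uniform")
  cust <- substrate_profile(g, "custom", rho = rep(1, 100), Ntot = 5)
  expect_equal(sum(cust$rho) * g$dx, 5, tolerance = 1e-12)
  expect_error(substrate_profile(g, "uniform", Ntot = -1), "non-negative")
})

test_that("uniform substrate gives the local-equilibrium solution", {
  g <- rd_grid(2, 200)
  kin <- kinetic_params(D = 3, kon = 0.7, koffR = 0.5, koffW = 4)
  s <- substrate_profile(g, "uniform", Ntot = 10)
  p <- solve_linear_steady_state(g, kin, s, s, rhoE = 2)
  expect_equal(p$rhoER, rep(kin$kon * 5 * 2 / kin$koffR, 200),
               tolerance = 1e-12)
  expect_equal(p$rhoEW, rep(kin$kon * 5 * 2 / kin$koffW, 200),
               tolerance = 1e-12)
})

test_that("equal off-rates give identical complex profiles (symmetry)", {
  g <- rd_grid(1, 300)
  kin <- kinetic_params(D = 1, koffR = 2, koffW = 2)
  s <- substrate_profile(g, "delta", Ntot = 1)
  p <- solve_linear_steady_state(g, kin, s, s)
  expect_equal(p$rhoER, p$rhoEW, tolerance = 1e-12)
})

test_that("PDE, closed form and lattice oracle agree (triple cross-check)", {
  # frozen example: koffR=1, koffW=10, tauD=1
  eta_pde <- pde_delta_eta(1, 10, 1, N = 2000)
  eta_cf <- fidelity_ideal_localization(1, 10, 1)
  eta_or <- lattice_markov_oracle(kinetic_params(D = 1), 2000, 1)
  expect_equal(eta_pde, 31.7277, tolerance = 1e-4)
  expect_equal(eta_pde / eta_cf, 1, tolerance = 1e-2)
  expect_equal(eta_pde / eta_or, 1, tolerance = 1e-2)
  # lighter grid over the spec's (tauD*koffR, etaEq) matrix
  for (tk in c(0.1, 10)) {
    for (ee in c(2, 100)) {
      eta_pde <- pde_delta_eta(1, ee, tk, N = 800)
      eta_cf <- fidelity_ideal_localization(1, ee, tk)
      eta_or <- lattice_markov_oracle(kinetic_params(D = 1, koffW = ee),
                                      800, tk)
      expect_equal(eta_pde / eta_cf, 1, tolerance = 1e-2)
      expect_equal(eta_pde / eta_or, 1, tolerance = 1e-2)
    }
  }
})

test_that("lattice oracle degenerate limits", {
  kin <- kinetic_params(D = 1, koffR = 3, koffW = 3)
  expect_equal(lattice_markov_oracle(kin, 200, 1), 1, tolerance = 1e-12)
  kin2 <- kinetic_params(D = 1, koffR = 1e-9, koffW = 1e-9)
  expect_equal(lattice_markov_oracle(kin2, 200, 1), 1, tolerance = 1e-6)
})

test_that("fast-diffusion limit reaches etaEq within 0.1% for all profile kinds", {
  tauD <- 1e-4 / 10                       # tauD * koffW = 1e-4
  g <- rd_grid(1, 500)
  kin <- kinetic_params(D = 1 / tauD, koffR = 1, koffW = 10)
  for (kind in c("delta", "exponential", "uniform")) {
    s <- substrate_profile(g, kind, lambdaS = 0.1, Ntot = 1)
    p <- solve_linear_steady_state(g, kin, s, s)
    expect_equal(p$rhoER[500] / p$rhoEW[500], 10, tolerance = 1e-3)
  }
})

test_that("grid convergence: default-scenario fidelity stable under refinement", {
  e1 <- pde_delta_eta(1, 10, 1, N = 1000)
  e2 <- pde_delta_eta(1, 10, 1, N = 2000)
  expect_lt(abs(e2 / e1 - 1), 1e-3)
})

test_that("finite lambdaS fidelity is non-monotonic in tauD and re-approaches etaEq", {
  g <- rd_grid(1, 500)
  s <- substrate_profile(g, "exponential", lambdaS = 0.1, Ntot = 1)
  eta <- vapply(10^seq(-1, 4, length.out = 18), function(tauD) {
    kin <- kinetic_params(D = 1 / tauD, koffR = 1, koffW = 10)
    p <- solve_linear_steady_state(g, kin, s, s)
    p$rhoER[500] / p$rhoEW[500]
  }, numeric(1))
  imax <- which.max(eta)
  expect_gt(imax, 1)
  expect_lt(imax, 18)                     # interior maximum
  expect_gt(eta[imax], 10)                # genuine enhancement at the peak
  expect_lt(eta[18], eta[imax] / 5)       # decays past the optimum
  # complex profiles approach the substrate shape at very large tauD
  # (penetration depth sqrt(D/koff) far below lambdaS)
  kin <- kinetic_params(D = 1e-6, koffR = 1, koffW = 10)
  p <- solve_linear_steady_state(g, kin, s, s)
  shapeR <- p$rhoER / sum(p$rhoER)
  shapeS <- s$rho / sum(s$rho)
  expect_lt(max(abs(shapeR - shapeS)), 0.02 * max(shapeS))
})

test_that("speed/fidelity extraction: equilibrium reference and v_norm limits", {
  g <- rd_grid(1, 500)
  kin <- kinetic_params(D = 1, koffR = 1, koffW = 10)
  uni <- substrate_profile(g, "uniform", Ntot = 1)
  sf <- compute_speed_fidelity(solve_linear_steady_state(g, kin, uni, uni))
  expect_equal(sf$eta, 10, tolerance = 1e-10)
  expect_equal(sf$v_norm, 1, tolerance = 1e-10)
  expect_equal(sf$n_eff, 0, tolerance = 1e-8)
  # delta substrate: v_norm = kappa L / sinh(kappa L), decreasing in tauD
  del <- substrate_profile(g, "delta", Ntot = 1)
  v <- vapply(c(0.01, 0.1, 1, 10, 100), function(tauD) {
    k <- kinetic_params(D = 1 / tauD, koffR = 1, koffW = 10)
    compute_speed_fidelity(solve_linear_steady_state(g, k, del, del))$v_norm
  }, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_lt(v[1], 1 + 1e-9)
  expect_equal(v[3], 1 / sinh(1), tolerance = 1e-3)
  # finite-catalysis mode: readout is the integrated sink
  kinf <- kinetic_params(D = 1, koffR = 1, koffW = 10, r = 5)
  pf <- solve_linear_steady_state(g, kinf, del, del, catalysis_mode = "finite")
  sff <- compute_speed_fidelity(pf)
  expect_equal(sff$vR, kinf$r * pf$rhoER[500] * g$dx)
  expect_gt(sff$eta, 1)
})

test_that("nonlinear solver: dilute agreement, mass conservation, load monotonicity", {
  g <- rd_grid(1, 400)
  kin <- kinetic_params(D = 1, koffR = 1, koffW = 10)
  s_dilute <- substrate_profile(g, "exponential", lambdaS = 0.1, Ntot = 1e-3)
  lin <- solve_linear_steady_state(g, kin, s_dilute, s_dilute, rhoE = 1)
  nl <- solve_nonlinear_steady_state(g, kin, s_dilute, s_dilute, Etot = 1)
  expect_true(nl$converged)
  eta_lin <- lin$rhoER[400] / lin$rhoEW[400]
  eta_nl <- nl$rhoER[400] / nl$rhoEW[400]
  expect_equal(eta_nl / eta_lin, 1, tolerance = 5e-3)
  # enzyme mass conserved
  expect_equal(sum(nl$rhoE + nl$rhoER + nl$rhoEW) * g$dx, 1,
               tolerance = 1e-8)
  # total enzyme density uniform at the joint steady state
  tot <- nl$rhoE + nl$rhoER + nl$rhoEW
  expect_lt(diff(range(tot)) / mean(tot), 1e-6)
  # fidelity non-increasing as substrate load scales x{1, 10, 100}
  etas <- vapply(c(1, 10, 100) * 0.05, function(Nt) {
    s <- substrate_profile(g, "exponential", lambdaS = 0.1, Ntot = Nt)
    n <- solve_nonlinear_steady_state(g, kin, s, s, Etot = 1)
    n$rhoER[400] / n$rhoEW[400]
  }, numeric(1))
  expect_true(all(diff(etas) <= 0))
  expect_true(all(nl$rhoE >= 0) && all(nl$rhoER >= 0) && all(nl$rhoEW >= 0))
})
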