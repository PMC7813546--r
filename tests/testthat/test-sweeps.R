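# Sweeps, Pareto front and optimum location.

sweep_scenario <- function(N = 400) {
  list(grid = rd_grid(1, N),
       kinetics = kinetic_params(D = 1, koffR = 1, koffW = 10),
       Ntot = 1, rhoE = 1)
}

test_that("a 1x1x1 sweep reduces to a single consistent solve", {
  sc <- sweep_scenario()
  spec <- sweep_spec(tauD_grid = 2, lambdaS_grid = 0.1, r_grid = 1e-6,
                     kinetics = sc$kinetics, grid = sc$grid)
  tab <- run_sweep(spec)
  expect_equal(nrow(tab), 1L)
  kin <- sc$kinetics; kin$D <- 1 / 2
  s <- substrate_profile(sc$grid, "exponential", lambdaS = 0.1, Ntot = 1)
  sf <- compute_speed_fidelity(solve_linear_steady_state(sc$grid, kin, s, s))
  expect_equal(tab$eta, sf$eta, tolerance = 1e-12)
  expect_equal(tab$v_norm, sf$v_norm, tolerance = 1e-12)
})

test_that("ideal-localization sweep reproduces the closed-form fidelity family", {
  # koffW/koffR = 100 at tauD*koffR = 100 has a boundary layer of width
  # 1/100 of the box; N = 2500 keeps the discrete decay rate within 1%
  for (ratio in c(10, 100)) {
    N <- if (ratio == 10) 800 else 2500
    spec <- sweep_spec(tauD_grid = 10^seq(-2, 2, length.out = 9),
                       lambdaS_grid = 0, r_grid = 1e-6,
                       kinetics = kinetic_params(D = 1, koffW = ratio),
                       grid = rd_grid(1, N))
    tab <- run_sweep(spec)
    cf <- fidelity_ideal_localization(1, ratio, tab$tauD)
    expect_equal(tab$eta / cf, rep(1, 9), tolerance = 2e-2)
  }
})

test_that("bulk sweep satisfies eta >= 1 and the dissipation bound", {
  spec <- sweep_spec(tauD_grid = 10^seq(-2, 2, length.out = 8),
                     lambdaS_grid = c(0, 0.04, 0.1, 0.4, Inf),
                     kinetics = kinetic_params(D = 1),
                     grid = rd_grid(1, 300))
  tab <- run_sweep(spec)
  expect_equal(nrow(tab), 40L)
  expect_true(all(tab$flag == ""))
  expect_true(all(tab$eta >= 1 - 1e-12))
  fin <- tab[is.finite(tab$lambdaS) & tab$lambdaS > 0, ]
  expect_true(all(log(fin$eta / 10) <= 1 / fin$lambdaS * (1 + 1e-9)))
  # delta rows carry infinite gradient-maintenance cost by convention
  expect_true(all(is.infinite(tab$P[tab$lambdaS == 0])))
  expect_true(all(abs(tab$P[is.infinite(tab$lambdaS)]) < 1e-10))
})

test_that("pareto front: dominance, ties, invariance under duplication/permutation", {
  single <- data.frame(v_norm = 0.5, eta = 10)
  expect_equal(nrow(pareto_front(single)), 1L)
  two <- data.frame(v_norm = c(0.5, 0.4), eta = c(10, 5))
  expect_equal(nrow(pareto_front(two)), 1L)
  expect_equal(pareto_front(two)$v_norm, 0.5)
  pts <- data.frame(v_norm = c(0.9, 0.7, 0.5, 0.3, 0.8),
                    eta = c(1, 5, 20, 10, 2))
  f <- pareto_front(pts)
  expect_equal(f$v_norm, c(0.9, 0.8, 0.7, 0.5))
  expect_true(all(diff(f$v_norm) < 0) && all(diff(f$eta) > 0))
  # duplication and permutation leave the front unchanged (ties kept)
  set.seed(7)
  for (rep in 1:3) {
    pts2 <- rbind(pts, pts[sample(nrow(pts), 3), ])
    pts2 <- pts2[sample(nrow(pts2)), ]
    f2 <- pareto_front(pts2)
    expect_equal(unique(f2[c("v_norm", "eta")]), f[c("v_norm", "eta")],
                 ignore_attr = TRUE)
  }
  # agreement with the brute-force reference on random clouds
  set.seed(11)
  cloud <- data.frame(v_norm = stats::runif(60), eta = stats::runif(60))
  expect_equal(pareto_front(cloud)[c("v_norm", "eta")],
               pareto_bruteforce(cloud)[c("v_norm", "eta")],
               ignore_attr = TRUE)
  expect_error(pareto_front(data.frame(v_norm = NA_real_, eta = 1)),
               "finite")
})

test_that("the sweep's front coincides with the ideal-localization curve", {
  spec <- sweep_spec(tauD_grid = 10^seq(-1, 1, length.out = 7),
                     lambdaS_grid = c(0, 0.1, 0.4),
                     kinetics = kinetic_params(D = 1),
                     grid = rd_grid(1, 300))
  tab <- run_sweep(spec)
  f <- pareto_front(tab)
  # every front point lies on (or within 2% of) the dense lambdaS -> 0
  # curve, whose speed and fidelity are known in closed form:
  # v_norm = kappa L / sinh(kappa L), eta from the sinh ratio
  tauD <- 10^seq(-4, 3, length.out = 400)
  aR <- sqrt(tauD)
  v_ideal <- aR / sinh(aR)
  eta_ideal <- fidelity_ideal_localization(1, 10, tauD)
  near <- vapply(seq_len(nrow(f)), function(i) {
    any(v_ideal >= f$v_norm[i] * (1 - 0.02) &
          eta_ideal >= f$eta[i] * (1 - 0.02))
  }, logical(1))
  expect_true(all(near))
})

test_that("fidelity optimum: interior maxima, estimate agreement, edge flag", {
  sc <- sweep_scenario(N = 500)
  eta_max <- c()
  for (lam in c(0.04, 0.1, 0.4)) {
    opt <- locate_fidelity_optimum(lam, sc)
    expect_false(opt$edge)
    est <- optimal_tauD_estimate(10, 1, lam, 1)
    expect_lt(abs(log10(opt$tauD_star / est)), 1)  # within a factor of 10
    eta_max <- c(eta_max, opt$eta_max)
  }
  # peak fidelity decreases with weaker localization
  expect_true(all(diff(eta_max) < 0))
  # near-ideal localization: no interior maximum, flagged edge
  opt0 <- locate_fidelity_optimum(1e-4, sc)
  expect_true(opt0$edge)
})

test_that("window invariant: bulk of the fidelity rise between the two scales", {
  g <- rd_grid(1, 500)
  tauD <- 10
  kin <- kinetic_params(D = 1 / tauD, koffR = 1, koffW = 10)
  ratios <- 10^seq(-1.5, 2.5, length.out = 40)   # L/lambdaS
  leta <- vapply(ratios, function(rr) {
    s <- substrate_profile(g, "exponential", lambdaS = 1 / rr, Ntot = 1)
    p <- solve_linear_steady_state(g, kin, s, s)
    log(p$rhoER[g$N] / p$rhoEW[g$N])
  }, numeric(1))
  e_uni <- log(10)
  e_delta <- fidelity_ideal_localization(1, 10, tauD, log = TRUE)
  lo <- sqrt(tauD * 1) / 3
  hi <- 3 * sqrt(tauD * 10)
  rise_in_window <- stats::approx(log(ratios), leta, log(hi))$y -
    stats::approx(log(ratios), leta, log(lo))$y
  expect_gt(rise_in_window / (e_delta - e_uni), 0.8)
})
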