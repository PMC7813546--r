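# Steady-state solvers for the 1D reaction-diffusion system
#
#   d rhoES/dt = D rhoES'' - koffS rhoES + kon rhoS(x) rhoE - c(x) rhoES
#
# on [0, L] with no-flux boundaries, discretized by second-order central
# differences on the cell-centered grid (ghost-cell reflection). Each
# substrate species gives one tridiagonal linear system, solved directly
# with a sparse LU factorization.

# sparse operator  -D * Laplacian + diag(sink)  (an M-matrix)
.rd_operator <- function(grid, D, sink) {
  N <- grid$N
  h <- D / grid$dx^2
  d <- rep(2 * h, N)
  d[c(1L, N)] <- h                       # reflecting ghost cells
  Matrix::bandSparse(N, N,
                     k = c(-1L, 0L, 1L),
                     diagonals = list(rep(-h, N - 1L), d + sink,
                                      rep(-h, N - 1L)))
}

.catalysis_sink <- function(grid, kinetics, catalysis_mode) {
  sink <- rep(0, grid$N)
  if (catalysis_mode == "finite") sink[grid$N] <- kinetics$r
  sink
}

#' Linearized steady state of the bound-enzyme densities
#'
#' Solves the steady-state complex profiles rhoER(x), rhoEW(x) in the
#' dilute-substrate regime, where the free-enzyme density is approximately
#' uniform (`rhoE` constant) and the two species decouple into independent
#' tridiagonal systems. The two substrates may have different profiles
#' (different localization length scales included).
#'
#' @param grid an [rd_grid].
#' @param kinetics a [kinetic_params] object; `D`, `kon`, off-rates and
#'   (in finite-catalysis mode) `r` are used.
#' @param substrateR,substrateW [substrate_profile] objects on `grid`.
#' @param rhoE uniform free-enzyme line density (molecules/um).
#' @param catalysis_mode `"slow"` (default): catalysis is a passive readout
#'   r * rhoES(L) that does not perturb the profiles, the regime of the
#'   main analysis. `"finite"`: a first-order sink of rate `r` acts in the
#'   rightmost cell, supporting arbitrary catalysis rates.
#' @return An object of class `complex_profiles` with fields `rhoER`,
#'   `rhoEW`, `rhoE`, plus the inputs, for downstream speed/fidelity and
#'   thermodynamic accounting.
#' @seealso [compute_speed_fidelity()], [solve_nonlinear_steady_state()]
#' @export
solve_linear_steady_state <- function(grid, kinetics, substrateR, substrateW,
                                      rhoE = 1,
                                      catalysis_mode = c("slow", "finite")) {
  stopifnot(inherits(grid, "rd_grid"), inherits(kinetics, "kinetic_params"),
            inherits(substrateR, "substrate_field"),
            inherits(substrateW, "substrate_field"))
  catalysis_mode <- match.arg(catalysis_mode)
  if (!is.numeric(rhoE) || !(length(rhoE) %in% c(1L, grid$N)) || any(rhoE < 0))
    stop("'rhoE' must be a non-negative scalar (or per-cell vector)",
         call. = FALSE)
  if (substrateR$grid$N != grid$N || substrateW$grid$N != grid$N)
    stop("substrate profiles must live on the same grid", call. = FALSE)
  sink <- .catalysis_sink(grid, kinetics, catalysis_mode)
  solve_one <- function(koff, rhoS) {
    A <- .rd_operator(grid, kinetics$D, koff + sink)
    b <- kinetics$kon * rhoS * rhoE
    if (all(b == 0)) return(rep(0, grid$N))
    as.numeric(Matrix::solve(A, b))
  }
  structure(list(
    rhoER = solve_one(kinetics$koffR, substrateR$rho),
    rhoEW = solve_one(kinetics$koffW, substrateW$rho),
    rhoE = rhoE,
    grid = grid, kinetics = kinetics,
    substrateR = substrateR, substrateW = substrateW,
    catalysis_mode = catalysis_mode,
    mode = "linear"
  ), class = "complex_profiles")
}

#' Self-consistent steady state with enzyme conservation
#'
#' Drops the uniform free-enzyme assumption: rhoE(x) satisfies its own
#' steady-state diffusion-reaction balance and the total enzyme amount is
#' conserved, integral(rhoE + rhoER + rhoEW) dx = Etot. Because free and
#' bound enzyme diffuse with the same D, the summed density is uniform at
#' steady state, which the damped fixed-point iteration exploits: solve the
#' complex systems at the current rhoE(x), reset
#' rhoE = Etot/L - rhoER - rhoEW (damped), rescale to exact conservation,
#' and repeat until the fidelity is stationary. This is the regime in which
#' abundant substrate sequesters enzyme near the source and degrades
#' proofreading.
#'
#' @inheritParams solve_linear_steady_state
#' @param Etot total enzyme amount (molecules, > 0).
#' @param tol relative fidelity change declaring convergence (default 1e-8).
#' @param max_iter iteration cap (default 1e4); exceeding it returns the
#'   last iterate with `converged = FALSE` and the residual history.
#' @param damping fraction of the new free-enzyme field accepted per
#'   iteration (0 < damping <= 1).
#' @return A `complex_profiles` object with per-cell `rhoE`, plus
#'   convergence metadata (`converged`, `iterations`, `residual`).
#' @export
solve_nonlinear_steady_state <- function(grid, kinetics, substrateR,
                                         substrateW, Etot,
                                         catalysis_mode = c("slow", "finite"),
                                         tol = 1e-8, max_iter = 1e4,
                                         damping = 0.5) {
  stopifnot(inherits(grid, "rd_grid"), inherits(kinetics, "kinetic_params"))
  catalysis_mode <- match.arg(catalysis_mode)
  if (!is.numeric(Etot) || Etot <= 0) stop("'Etot' must be > 0", call. = FALSE)
  N <- grid$N
  sink <- .catalysis_sink(grid, kinetics, catalysis_mode)
  AR <- .rd_operator(grid, kinetics$D, kinetics$koffR + sink)
  AW <- .rd_operator(grid, kinetics$D, kinetics$koffW + sink)
  rhoE <- rep(Etot / grid$L, N)
  eta_prev <- NA_real_
  residual <- NA_real_
  converged <- FALSE
  iter <- 0L
  rhoER <- rhoEW <- rep(0, N)
  while (iter < max_iter) {
    iter <- iter + 1L
    rhoER <- as.numeric(Matrix::solve(AR, kinetics$kon * substrateR$rho * rhoE))
    rhoEW <- as.numeric(Matrix::solve(AW, kinetics$kon * substrateW$rho * rhoE))
    # the system is linear and homogeneous in the enzyme fields: rescale the
    # triple to exact conservation BEFORE forming the update target, so the
    # clamp below only acts where the budget is genuinely exceeded locally
    scl <- Etot / (sum(rhoE + rhoER + rhoEW) * grid$dx)
    rhoE <- rhoE * scl; rhoER <- rhoER * scl; rhoEW <- rhoEW * scl
    eta <- rhoER[N] / rhoEW[N]
    residual <- abs(eta - eta_prev) / abs(eta)
    if (is.finite(residual) && residual < tol) { converged <- TRUE; break }
    eta_prev <- eta
    # total enzyme density is uniform at the joint steady state
    target <- pmax(Etot / grid$L - rhoER - rhoEW, 0)
    rhoE <- (1 - damping) * rhoE + damping * target
  }
  if (!converged)
    warning(sprintf(
      "fixed-point iteration not converged after %d iterations (residual %g)",
      iter, residual), call. = FALSE)
  structure(list(
    rhoER = rhoER, rhoEW = rhoEW, rhoE = rhoE,
    grid = grid, kinetics = kinetics,
    substrateR = substrateR, substrateW = substrateW,
    catalysis_mode = catalysis_mode,
    mode = "nonlinear", Etot = Etot,
    converged = converged, iterations = iter, residual = residual
  ), class = "complex_profiles")
}

#' @export
print.complex_profiles <- function(x, ...) {
  cat(sprintf("Steady-state complex profiles (%s solver, %s catalysis)\n",
              x$mode, x$catalysis_mode))
  cat(sprintf("  grid: N = %d, L = %g um\n", x$grid$N, x$grid$L))
  cat(sprintf("  rhoER(L) = %.6g, rhoEW(L) = %.6g, eta = %.6g\n",
              x$rhoER[x$grid$N], x$rhoEW[x$grid$N],
              x$rhoER[x$grid$N] / x$rhoEW[x$grid$N]))
  invisible(x)
}

#' Production speeds, fidelity and effective proofreading depth
#'
#' Extracts the speed/fidelity summary from solved complex profiles. In the
#' slow-catalysis regime the production rate per substrate is the passive
#' readout vS = r * rhoES(L) (density in the last cell); in finite-catalysis
#' mode it is the integrated catalytic sink r * rhoES(L) * dx. The speed is
#' normalized by `veq`, the right-substrate speed recomputed for a uniform
#' substrate profile of identical total amount (the equilibrium reference),
#' so that `v_norm = 1` marks the no-gradient operating point.
#'
#' @param profiles a `complex_profiles` object from either solver.
#' @return An object of class `speed_fidelity`: fields `vR`, `vW`, `eta`,
#'   `v_norm`, `n_eff` (effective proofreading steps; `NA` when
#'   etaEq = 1), `veq`, and `eta_infinite` flag (TRUE when vW = 0).
#' @export
compute_speed_fidelity <- function(profiles) {
  stopifnot(inherits(profiles, "complex_profiles"))
  g <- profiles$grid
  kin <- profiles$kinetics
  N <- g$N
  readout <- function(p) {
    if (p$catalysis_mode == "finite")
      c(kin$r * p$rhoER[N] * g$dx, kin$r * p$rhoEW[N] * g$dx)
    else
      c(kin$r * p$rhoER[N], kin$r * p$rhoEW[N])
  }
  v <- readout(profiles)
  vR <- v[1]; vW <- v[2]
  eta_infinite <- vW == 0 && vR > 0
  eta <- if (vW == 0) (if (vR > 0) Inf else NaN) else vR / vW
  # equilibrium reference: same solver, uniform substrates, same totals
  uniR <- substrate_profile(g, "uniform", Ntot = profiles$substrateR$Ntot)
  uniW <- substrate_profile(g, "uniform", Ntot = profiles$substrateW$Ntot)
  ref <- if (profiles$mode == "nonlinear")
    solve_nonlinear_steady_state(g, kin, uniR, uniW, Etot = profiles$Etot,
                                 catalysis_mode = profiles$catalysis_mode)
  else
    solve_linear_steady_state(g, kin, uniR, uniW, rhoE = profiles$rhoE,
                              catalysis_mode = profiles$catalysis_mode)
  veq <- readout(ref)[1]
  etaEq <- kin$koffW / kin$koffR
  # inline step count: eta marginally below etaEq is numerical noise here,
  # not worth the below-equilibrium warning effective_steps_exact() raises
  n_eff <- if (etaEq > 1 && is.finite(eta) && eta > 0)
    (log(eta) - log(etaEq)) / log(etaEq) else NA_real_
  structure(list(vR = vR, vW = vW, eta = eta, v_norm = vR / veq, veq = veq,
                 n_eff = n_eff, etaEq = etaEq, eta_infinite = eta_infinite),
            class = "speed_fidelity")
}

#' @export
print.speed_fidelity <- function(x, ...) {
  cat("Speed-fidelity summary\n")
  cat(sprintf("  vR = %.6g, vW = %.6g (1/s)\n", x$vR, x$vW))
  cat(sprintf("  eta = %.6g (etaEq = %g), v/veq = %.6g, n_eff = %.4g\n",
              x$eta, x$etaEq, x$v_norm, x$n_eff))
  invisible(x)
}

#' Absorbing Markov-chain fidelity oracle
#'
#' Independent discrete check of the continuum solution in the ideal
#' localization limit. A single complex is created at site 1 of an M-site
#' chain, hops to nearest neighbours at rate h = D/dx^2 (reflecting ends)
#' and unbinds (is absorbed) at rate koffS. The expected time spent at the
#' last site before absorption follows from the fundamental matrix of the
#' absorbing chain, obtained by one tridiagonal solve of
#' (koffS I + h Lap) t = e1. The fidelity is the ratio of last-site
#' occupancies for the right and wrong substrates, and converges to
#' [fidelity_ideal_localization()] as M grows.
#'
#' @param kinetics a [kinetic_params] object (off-rates used; the hop rate
#'   is fixed by `tauD` and `grid_sites`, not by `D` directly).
#' @param grid_sites number of lattice sites M (>= 50).
#' @param tauD diffusion time scale across the chain (s).
#' @return Fidelity (dimensionless).
#' @export
lattice_markov_oracle <- function(kinetics, grid_sites = 2000, tauD) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  M <- as.integer(grid_sites)
  if (is.na(M) || M < 50L) stop("'grid_sites' must be >= 50", call. = FALSE)
  if (!is.numeric(tauD) || length(tauD) != 1L || tauD <= 0)
    stop("'tauD' must be a single positive time", call. = FALSE)
  # L = 1, D = 1/tauD: only tauD = L^2/D matters
  dx <- 1 / M
  h <- (1 / tauD) / dx^2
  occ_last <- function(koff) {
    d <- rep(koff + 2 * h, M)
    d[c(1L, M)] <- koff + h
    A <- Matrix::bandSparse(M, M, k = c(-1L, 0L, 1L),
                            diagonals = list(rep(-h, M - 1L), d,
                                             rep(-h, M - 1L)))
    as.numeric(Matrix::solve(A, c(1, rep(0, M - 1L))))[M]
  }
  occ_last(kinetics$koffR) / occ_last(kinetics$koffW)
}
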