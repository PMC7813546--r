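# Biochemically explicit gradient formation: a membrane kinase at x = 0
# phosphorylates inactive substrate S into its active form S*, a
# delocalized cytoplasmic phosphatase dephosphorylates S* everywhere at
# rate kp, and the proofreading enzyme binds S* only. At negligible enzyme
# load the S* profile is exponential with length scale sqrt(D/kp); at high
# load the enzymatic flux outruns the phosphatase and the gradient -- and
# with it proofreading -- collapses.
#
# With constant free-enzyme density the per-species system (S, S*, ES*) is
# linear, and all three species share one diffusion constant, so the summed
# density is uniform at steady state; S is eliminated as
# S = Stot/L - S* - ES* and the remaining (S*, ES*) fields solve one sparse
# 2N x 2N linear system per species. The kinase is a boundary flux
# kkin * S(0), represented as a surface reaction of rate kkin/dx confined
# to the first cell.

#' Parameters of the kinase/phosphatase gradient model
#'
#' Defaults follow literature-constrained values for cytoplasmic signaling
#' proteins: kp = 5/s (phosphatase rates span roughly 0.1-100/s; values
#' outside that range are flagged), D = 1 um^2/s for every protein,
#' L = 10 um, off-rates 0.1/s and 1/s for the right and wrong substrate
#' (etaEq = 10). The enzyme load enters only through the compound
#' first-order rate kon*rhoE (1/s).
#'
#' @param kp dephosphorylation rate (1/s).
#' @param kkin membrane phosphorylation rate constant (um/s); the default
#'   1e3 makes re-activation at the membrane effectively instantaneous, so
#'   the low-load gradient shape depends only on D and kp.
#' @param D common diffusion constant (um^2/s).
#' @param L,N compartment length (um) and grid resolution.
#' @param koffR,koffW substrate off-rates (1/s).
#' @param kon_rhoE enzyme activity: binding rate constant times free-enzyme
#'   density (1/s).
#' @param StotR,StotW total substrate amounts per species (molecules).
#' @param r catalysis readout rate (1/s); cancels from the fidelity.
#' @return Object of class `kp_params`.
#' @export
kp_params <- function(kp = 5, kkin = 1e3, D = 1, L = 10, N = 1000,
                      koffR = 0.1, koffW = 1, kon_rhoE = 1e-3,
                      StotR = 1, StotW = 1, r = 1e-6 * koffR) {
  for (nm in c("kp", "kkin", "D", "L", "koffR", "koffW", "r"))
    if (!is.numeric(get(nm)) || get(nm) <= 0)
      stop("'", nm, "' must be positive", call. = FALSE)
  if (kon_rhoE < 0) stop("'kon_rhoE' must be non-negative", call. = FALSE)
  if (koffW < koffR) stop("'koffW' must be >= 'koffR'", call. = FALSE)
  if (kp < 0.1 || kp > 100)
    warning("kp = ", kp, " 1/s lies outside the 0.1-100 1/s range reported ",
            "for phosphatases", call. = FALSE)
  structure(list(kp = kp, kkin = kkin, D = D, L = L, N = as.integer(N),
                 koffR = koffR, koffW = koffW, kon_rhoE = kon_rhoE,
                 StotR = StotR, StotW = StotW, r = r),
            class = "kp_params")
}

# one species: solve the coupled (active substrate a, complex C) system
.kp_solve_species <- function(grid, D, kp, kkin, koff, kE, Stot) {
  N <- grid$N
  dx <- grid$dx
  h <- D / dx^2
  lap_d <- rep(2 * h, N); lap_d[c(1L, N)] <- h
  kb <- kkin / dx                          # surface reaction, first cell
  # block A (a-rows): -D Lap + diag(kp + kE) + kb e1e1'   | -koff I + kb e1e1'
  # block C (C-rows): -kE I                               | -D Lap + diag(koff)
  iA <- c(2:N, 1:N, 1:(N - 1))             # sub/main/super of -D Lap
  jA <- c(1:(N - 1), 1:N, 2:N)
  lap_x <- c(rep(-h, N - 1), lap_d, rep(-h, N - 1))
  ii <- jj <- xx <- list()
  add <- function(i, j, x) {
    ii[[length(ii) + 1L]] <<- i; jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- x
  }
  # a-rows: -D Lap a
  add(iA, jA, lap_x)
  # a-rows: + (kp + kE) a, + kb (a1 + C1) at cell 1
  add(1:N, 1:N, rep(kp + kE, N))
  add(1L, 1L, kb)
  add(1L, N + 1L, kb)
  # a-rows: - koff C
  add(1:N, 1:N + N, rep(-koff, N))
  # C-rows: -D Lap C + koff C - kE a
  add(iA + N, jA + N, lap_x)
  add(1:N + N, 1:N + N, rep(koff, N))
  add(1:N + N, 1:N, rep(-kE, N))
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(2L * N, 2L * N))
  b <- c(kb * Stot / grid$L, rep(0, 2L * N - 1L))
  z <- as.numeric(Matrix::solve(A, b))
  a <- z[1:N]
  C <- z[1:N + N]
  list(a = a, C = C, s = Stot / grid$L - a - C)
}

#' Steady state of the kinase/phosphatase proofreading model
#'
#' Solves, per substrate species, the coupled steady state of inactive
#' substrate S (diffuses, re-phosphorylated only at the x = 0 membrane),
#' active substrate S* (diffuses, dephosphorylated at rate kp, binds the
#' enzyme at rate kon*rhoE), and complex ES* (diffuses, releases S* at
#' koffS, slow-catalysis readout at x = L). Kinase and phosphatase act
#' identically on right and wrong substrates; only the off-rates differ.
#' Total substrate is conserved per species.
#'
#' @param params a [kp_params] object.
#' @return Object of class `kp_state`: per-species lists `R` and `W`
#'   (fields `s`, `a`, `C` on the grid), `grid`, `eta`, `eta_over_etaEq`,
#'   `vR`, `vW`, and `lambda_fit` (exponential decay length fitted to the
#'   right-substrate active profile, um).
#' @export
solve_kp_steady_state <- function(params) {
  stopifnot(inherits(params, "kp_params"))
  g <- rd_grid(params$L, params$N)
  R <- .kp_solve_species(g, params$D, params$kp, params$kkin, params$koffR,
                         params$kon_rhoE, params$StotR)
  W <- .kp_solve_species(g, params$D, params$kp, params$kkin, params$koffW,
                         params$kon_rhoE, params$StotW)
  for (sp in list(R, W)) {
    if (min(sp$s, sp$a, sp$C) < -1e-9 * max(sp$a))
      warning("negative species density at convergence", call. = FALSE)
  }
  vR <- params$r * R$C[g$N]
  vW <- params$r * W$C[g$N]
  etaEq <- params$koffW / params$koffR
  structure(list(R = R, W = W, grid = g, params = params,
                 vR = vR, vW = vW, eta = vR / vW,
                 eta_over_etaEq = (vR / vW) / etaEq,
                 lambda_fit = fit_gradient_length(g$x, R$a)),
            class = "kp_state")
}

#' @export
print.kp_state <- function(x, ...) {
  cat("Kinase/phosphatase gradient model, steady state\n")
  cat(sprintf("  kon*rhoE = %g 1/s, kp = %g 1/s\n",
              x$params$kon_rhoE, x$params$kp))
  cat(sprintf("  fitted S* decay length = %.4g um (sqrt(D/kp) = %.4g um)\n",
              x$lambda_fit, sqrt(x$params$D / x$params$kp)))
  cat(sprintf("  eta = %.6g (eta/etaEq = %.4g)\n", x$eta, x$eta_over_etaEq))
  invisible(x)
}

#' Exponential decay length fitted to a profile
#'
#' Least-squares slope of log(profile) over the cells where the profile
#' exceeds exp(-4) of its maximum (about four decay lengths). Returns `Inf`
#' for flat or rising profiles.
#'
#' @param x cell-center coordinates (um).
#' @param a non-negative profile values.
#' @return Fitted decay length (um).
#' @export
fit_gradient_length <- function(x, a) {
  ok <- a > max(a) * exp(-4) & a > 0
  if (sum(ok) < 3L) return(NA_real_)
  slope <- unname(stats::coef(stats::lm.fit(cbind(1, x[ok]), log(a[ok])))[2])
  if (slope >= 0) Inf else -1 / slope
}

#' Fidelity as a function of enzyme activity
#'
#' Scans the compound enzyme activity kon*rhoE and records the fidelity and
#' the fitted active-substrate gradient length. At low activity the
#' gradient survives and the fidelity approaches the exponential-profile
#' reference prediction; at high activity the enzymatic flux outruns the
#' phosphatase, the gradient homogenizes and proofreading is lost.
#'
#' @param params a [kp_params] object (its `kon_rhoE` is overridden).
#' @param konRhoE_list activities to scan (1/s).
#' @return data.frame with columns `konRhoE`, `eta`, `eta_over_etaEq`,
#'   `gradient_lengthscale_fit`, `flag` (per-row failure messages).
#' @export
fidelity_vs_activity <- function(params, konRhoE_list) {
  stopifnot(inherits(params, "kp_params"))
  rows <- lapply(konRhoE_list, function(kE) {
    p <- params
    p$kon_rhoE <- kE
    flag <- ""
    st <- tryCatch(solve_kp_steady_state(p),
                   error = function(e) { flag <<- conditionMessage(e); NULL })
    if (is.null(st))
      data.frame(konRhoE = kE, eta = NA_real_, eta_over_etaEq = NA_real_,
                 gradient_lengthscale_fit = NA_real_, flag = flag)
    else
      data.frame(konRhoE = kE, eta = st$eta,
                 eta_over_etaEq = st$eta_over_etaEq,
                 gradient_lengthscale_fit = st$lambda_fit, flag = flag)
  })
  do.call(rbind, rows)
}

#' Exponential-profile reference fidelity
#'
#' The fidelity the minimal explanatory model predicts for an exponential
#' substrate profile with the gradient length scale lambdaS = sqrt(D/kp)
#' set by the kinase/phosphatase system, at the same kinetics and geometry.
#' This is the low-activity ceiling of [fidelity_vs_activity()].
#'
#' @param params a [kp_params] object.
#' @return Fidelity eta (dimensionless).
#' @export
reference_exponential_prediction <- function(params) {
  stopifnot(inherits(params, "kp_params"))
  g <- rd_grid(params$L, params$N)
  kin <- kinetic_params(D = params$D, kon = 1, koffR = params$koffR,
                        koffW = params$koffW, r = params$r)
  lam <- sqrt(params$D / params$kp)
  subR <- substrate_profile(g, "exponential", lambdaS = lam,
                            Ntot = params$StotR)
  subW <- substrate_profile(g, "exponential", lambdaS = lam,
                            Ntot = params$StotW)
  prof <- solve_linear_steady_state(g, kin, subR, subW, rhoE = 1)
  sf <- compute_speed_fidelity(prof)
  sf$eta
}
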