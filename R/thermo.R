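# Dissipation accounting. The enzyme itself consumes no fuel; the free
# energy cost of spatial proofreading is the minimum power any mechanism
# must spend to maintain the substrate gradient against the homogenizing
# net binding flux jS(x) = kon rhoS(x) rhoE - koffS rhoES(x):
#
#   P = sum_S integral jS(x) mu_S(x) dx,   mu_S(x) = kBT ln(rhoS(x)/rhoS(0)).
#
# kBT = 1 internally; all energies are reported in kBT units. In the
# slow-catalysis regime integral jS dx = 0, so P is independent of the
# mu reference; in finite-catalysis mode P is reported relative to
# mu(0) = 0 (flagged in the result).

#' Local chemical potential of a substrate profile
#'
#' mu(x) = kBT * ln(rhoS(x)/rhoS(0)), reported relative to the x = 0 end
#' (first cell) in kBT units. For an exponential profile of length scale
#' lambdaS this is exactly -x/lambdaS (up to the half-cell reference
#' offset, which cancels in all power integrals at steady state). Cells
#' with zero density get mu = -Inf and are flagged via the `"excluded"`
#' attribute.
#'
#' @param substrate a [substrate_profile] object.
#' @return Numeric vector mu(x) (kBT), attribute `excluded` marking
#'   zero-density cells.
#' @export
chemical_potential_profile <- function(substrate) {
  stopifnot(inherits(substrate, "substrate_field"))
  rho <- substrate$rho
  if (all(rho == 0)) stop("all-zero substrate profile has no defined mu",
                          call. = FALSE)
  ref <- rho[rho > 0][1]
  mu <- ifelse(rho > 0, log(rho / ref), -Inf)
  attr(mu, "excluded") <- which(rho == 0)
  mu
}

#' Net local substrate binding flux
#'
#' jS(x) = kon * rhoS(x) * rhoE - koffS * rhoES(x), per substrate, the net
#' rate density at which free substrate is consumed by binding. Positive
#' near the substrate source, negative where the enzyme releases substrate
#' into regions of low concentration -- the homogenizing flux the gradient
#' machinery must undo. In the slow-catalysis regime the integral over the
#' compartment vanishes at steady state.
#'
#' @param profiles a `complex_profiles` object.
#' @return A list with numeric vectors `jR` and `jW` (molecules/(um s)).
#' @export
net_binding_flux <- function(profiles) {
  stopifnot(inherits(profiles, "complex_profiles"))
  kin <- profiles$kinetics
  list(jR = kin$kon * profiles$substrateR$rho * profiles$rhoE -
         kin$koffR * profiles$rhoER,
       jW = kin$kon * profiles$substrateW$rho * profiles$rhoE -
         kin$koffW * profiles$rhoEW)
}

#' Minimum gradient-maintenance power
#'
#' Midpoint quadrature of P = sum_S integral jS(x) mu_S(x) dx on the
#' cell-centered grid (consistent with the finite-volume discretization).
#' Zero for a uniform profile; non-negative at steady state (second law).
#'
#' @param jR,jW net binding flux vectors (from [net_binding_flux()]).
#' @param mu chemical potential: a single vector shared by both substrates,
#'   or a list `list(muR, muW)` when the two substrates have different
#'   localization length scales.
#' @param grid the [rd_grid] the fluxes live on.
#' @return Power P in kBT/s.
#' @export
dissipated_power <- function(jR, jW, mu, grid) {
  stopifnot(inherits(grid, "rd_grid"))
  if (is.list(mu)) { muR <- mu[[1]]; muW <- mu[[2]] } else muR <- muW <- mu
  if (length(jR) != grid$N || length(jW) != grid$N ||
      length(muR) != grid$N || length(muW) != grid$N)
    stop("flux/potential vectors must match the grid length", call. = FALSE)
  termR <- jR * muR
  termW <- jW * muW
  # 0 * (-Inf) cells (no substrate, no flux) contribute nothing
  termR[jR == 0 & is.infinite(muR)] <- 0
  termW[jW == 0 & is.infinite(muW)] <- 0
  sum(termR + termW) * grid$dx
}

#' Full thermodynamic summary of a solved scenario
#'
#' Convenience wrapper computing the flux, potential, power, integrated
#' binding rate Jbind = kon * rhoE * integral(rhoS) dx (both substrates),
#' and the cost per binding event P/Jbind.
#'
#' @param profiles a `complex_profiles` object.
#' @return Object of class `thermo_result` with fields `muR`, `muW`, `jR`,
#'   `jW`, `P`, `Jbind`, `cost_per_binding`, `betaDeltaMu` (NA for custom
#'   profiles), and `reference_dependent` (TRUE in finite-catalysis mode,
#'   where P depends on the mu(0) = 0 convention).
#' @export
thermo_summary <- function(profiles) {
  stopifnot(inherits(profiles, "complex_profiles"))
  g <- profiles$grid
  kin <- profiles$kinetics
  j <- net_binding_flux(profiles)
  muR <- chemical_potential_profile(profiles$substrateR)
  muW <- chemical_potential_profile(profiles$substrateW)
  P <- dissipated_power(j$jR, j$jW, list(muR, muW), g)
  Jbind <- sum(kin$kon * profiles$rhoE *
                 (profiles$substrateR$rho + profiles$substrateW$rho)) * g$dx
  lamR <- profiles$substrateR$lambdaS
  bdm <- if (is.na(lamR)) NA_real_ else driving_force(g$L, max(lamR,
                                                               .Machine$double.xmin))
  structure(list(muR = muR, muW = muW, jR = j$jR, jW = j$jW, P = P,
                 Jbind = Jbind,
                 cost_per_binding = P / Jbind,
                 betaDeltaMu = bdm,
                 reference_dependent = profiles$catalysis_mode == "finite"),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("Thermodynamic summary (kBT units)\n")
  cat(sprintf("  P = %.6g kBT/s, Jbind = %.6g 1/s\n", x$P, x$Jbind))
  cat(sprintf("  cost per binding = %.6g kBT, betaDeltaMu = %.4g\n",
              x$cost_per_binding, x$betaDeltaMu))
  invisible(x)
}

#' Dissipation-fidelity curve under a varying driving force
#'
#' Sweeps the driving force betaDeltaMu = L/lambdaS at fixed diffusion time
#' and substrate amount by tuning the localization length lambdaS, solving
#' the linearized steady state at each point. Within the window
#' betaDeltaMu in [sqrt(tauD koffR), sqrt(tauD koffW)] most of the fidelity
#' enhancement accrues and ln(eta/etaEq) grows approximately linearly with
#' the cost per binding; at the window's upper end (large tauD) the cost
#' per binding approaches etaEq in kBT units.
#'
#' @param scenario a list with components `grid` ([rd_grid]), `kinetics`
#'   ([kinetic_params]), `Ntot` (total per substrate) and `rhoE`.
#' @param betaDeltaMu_list driving forces to scan (0 allowed: uniform
#'   profile, the equilibrium endpoint).
#' @return data.frame with columns `betaDeltaMu`, `lambdaS`, `power`,
#'   `Jbind`, `cost_per_binding`, `eta`, `eta_over_etaEq`.
#' @export
cost_and_fidelity_curve <- function(scenario, betaDeltaMu_list) {
  g <- scenario$grid
  kin <- scenario$kinetics
  rows <- lapply(betaDeltaMu_list, function(bdm) {
    lam <- if (bdm == 0) Inf else g$L / bdm
    sub <- substrate_profile(g, "exponential", lambdaS = lam,
                             Ntot = scenario$Ntot)
    prof <- solve_linear_steady_state(g, kin, sub, sub, rhoE = scenario$rhoE)
    th <- thermo_summary(prof)
    sf <- compute_speed_fidelity(prof)
    data.frame(betaDeltaMu = bdm, lambdaS = lam, power = th$P,
               Jbind = th$Jbind, cost_per_binding = th$cost_per_binding,
               eta = sf$eta, eta_over_etaEq = sf$eta / sf$etaEq)
  })
  do.call(rbind, rows)
}
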