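# Independent oracles and small fixtures shared across the test files.

# Discrete entropy production of the solved steady state: sum over every
# transition edge (binding/unbinding per cell, diffusion hops between
# neighbouring cells) of (forward flux - backward flux) * ln(flux ratio).
# Hop edges carry the occupancy part of the affinity; at steady state the
# total equals the continuum quadrature of the gradient-maintenance power.
ep_discrete <- function(profiles) {
  g <- profiles$grid
  kin <- profiles$kinetics
  one <- function(rhoS, rhoES, koff) {
    Jp <- kin$kon * rhoS * profiles$rhoE
    Jm <- koff * rhoES
    ok <- Jp > 0 | Jm > 0
    bind <- sum(((Jp - Jm) * log(Jp / Jm))[ok]) * g$dx
    h <- kin$D / g$dx^2
    f <- h * rhoES[-g$N]
    b <- h * rhoES[-1]
    hop <- sum((f - b) * log(f / b)) * g$dx
    bind + hop
  }
  one(profiles$substrateR$rho, profiles$rhoER, kin$koffR) +
    one(profiles$substrateW$rho, profiles$rhoEW, kin$koffW)
}

# Quadratic-time reference for the Pareto front (strict dominance).
pareto_bruteforce <- function(points) {
  keep <- sapply(seq_len(nrow(points)), function(i) {
    v <- points$v_norm[i]; e <- points$eta[i]
    !any(points$v_norm >= v & points$eta >= e &
           (points$v_norm > v | points$eta > e))
  })
  out <- points[keep & is.finite(points$v_norm) & is.finite(points$eta), ]
  out[order(-out$v_norm, out$eta), ]
}

# Fidelity of the linearized PDE solve for a delta-localized substrate.
pde_delta_eta <- function(koffR, koffW, tauD, N = 1000) {
  g <- rd_grid(1, N)
  kin <- kinetic_params(D = 1 / tauD, koffR = koffR, koffW = koffW)
  s <- substrate_profile(g, "delta", Ntot = 1)
  p <- solve_linear_steady_state(g, kin, s, s)
  p$rhoER[N] / p$rhoEW[N]
}
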