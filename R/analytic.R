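# Closed-form theory for the ideal-localization limit and its asymptotics.
#
# All formulas below are for the linearized steady state of the 1D
# reaction-diffusion system with substrates perfectly localized at x = 0
# (point source) and a reflecting boundary at x = L. The bound-enzyme
# density then obeys D rho'' = koff rho away from the source, giving
# rho(L) proportional to 1/(kappa sinh(kappa L)) with kappa = sqrt(koff/D),
# and the fidelity
#
#   eta = sqrt(etaEq) * sinh(sqrt(koffW tauD)) / sinh(sqrt(koffR tauD)).
#
# The sqrt(etaEq) prefactor is fixed by the fast-diffusion limit
# (eta -> etaEq as tauD -> 0) and verified against the lattice Markov oracle.

# log(sinh(x)) without overflow; accurate for small and large x
.logsinh <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-4
  out[small] <- log(x[small]) + x[small]^2 / 6
  xl <- x[!small]
  out[!small] <- xl + log1p(-exp(-2 * xl)) - log(2)
  out
}

.check_rates <- function(koffR, koffW) {
  if (any(!is.finite(koffR)) || any(koffR <= 0) ||
      any(!is.finite(koffW)) || any(koffW <= 0))
    stop("off-rates must be positive and finite", call. = FALSE)
  if (any(koffW < koffR - 1e-15 * koffR))
    stop("'koffW' must be >= 'koffR'", call. = FALSE)
}

#' Fidelity in the ideal substrate-localization limit
#'
#' Closed-form steady-state fidelity eta = vR/vW of the spatial proofreading
#' scheme when the substrates are perfectly localized at one end of the
#' compartment (lambdaS -> 0) and catalysis at the other end is slow:
#' \deqn{\eta = \sqrt{\eta_{eq}}\,
#'   \frac{\sinh\sqrt{k_{off}^W \tau_D}}{\sinh\sqrt{k_{off}^R \tau_D}},}
#' with \eqn{\eta_{eq} = k_{off}^W / k_{off}^R} and \eqn{\tau_D = L^2/D}.
#' As \eqn{\tau_D \to 0} the fidelity reduces to the equilibrium value
#' \eqn{\eta_{eq}}; for slow diffusion it grows exponentially with
#' \eqn{(\sqrt{k_{off}^W} - \sqrt{k_{off}^R})\sqrt{\tau_D}}.
#'
#' @param koffR,koffW substrate off-rates (1/s), `koffW >= koffR`.
#' @param tauD diffusion time scale L^2/D (s); vectorized. `tauD = 0` is
#'   accepted and returns the equilibrium fidelity (continuity limit).
#' @param log if `TRUE` return log(eta); use this for large
#'   `tauD * koffW` where eta itself overflows double precision.
#' @return Fidelity eta (or its natural log), same length as `tauD`.
#' @seealso [lattice_markov_oracle()] for the independent discrete check,
#'   [asymptotic_log_fidelity()] for the slow-diffusion exponent.
#' @examples
#' fidelity_ideal_localization(1, 10, 1)   # ~31.73
#' fidelity_ideal_localization(1, 10, 1e-6) # ~ etaEq = 10
#' @export
fidelity_ideal_localization <- function(koffR, koffW, tauD, log = FALSE) {
  .check_rates(koffR, koffW)
  if (any(!is.finite(tauD)) || any(tauD < 0))
    stop("'tauD' must be non-negative and finite", call. = FALSE)
  etaEq <- koffW / koffR
  logeta <- rep(base::log(etaEq), length.out = length(tauD))
  pos <- tauD > 0
  if (any(pos)) {
    aR <- sqrt(koffR * tauD[pos])
    aW <- sqrt(koffW * tauD[pos])
    logeta[pos] <- 0.5 * base::log(etaEq) + .logsinh(aW) - .logsinh(aR)
  }
  if (log) return(logeta)
  out <- exp(logeta)
  out[tauD == 0] <- etaEq               # exact at the continuity limit
  out
}

#' Slow-diffusion asymptotic log-fidelity
#'
#' Leading exponent of the fidelity in the slow-diffusion regime,
#' \eqn{\ln\eta \sim (\sqrt{k_{off}^W} - \sqrt{k_{off}^R})\sqrt{\tau_D}}.
#' The closed form [fidelity_ideal_localization()] differs from
#' `exp(exponent)` only by the algebraic prefactor
#' \eqn{\sqrt{\eta_{eq}}/1}, so their log-difference stays bounded as
#' `tauD` grows.
#'
#' @inheritParams fidelity_ideal_localization
#' @param warn_threshold warn when `tauD * koffR` falls below this value
#'   (default 5); the asymptotic regime requires `tauD * koffR >> 1`.
#' @return The exponent (dimensionless), vectorized over `tauD`.
#' @export
asymptotic_log_fidelity <- function(koffR, koffW, tauD, warn_threshold = 5) {
  .check_rates(koffR, koffW)
  if (any(!is.finite(tauD)) || any(tauD < 0))
    stop("'tauD' must be non-negative and finite", call. = FALSE)
  if (any(tauD * koffR < warn_threshold))
    warning("asymptotic form used below tauD * koffR = ", warn_threshold,
            "; accuracy degrades outside the slow-diffusion regime",
            call. = FALSE)
  (sqrt(koffW) - sqrt(koffR)) * sqrt(tauD)
}

#' Exact effective number of proofreading steps
#'
#' The number `n` of extra biochemical intermediates a traditional
#' proofreading scheme would need in order to match a given fidelity,
#' defined through eta/etaEq = etaEq^n, i.e.
#' `n = log(eta/etaEq)/log(etaEq)`.
#'
#' @param eta achieved fidelity (>= 0). Alternatively supply `log_eta`.
#' @param etaEq equilibrium fidelity, strictly > 1.
#' @param log_eta optional natural log of eta, for fidelities beyond double
#'   range; overrides `eta` when given.
#' @return n (dimensionless); negative values (eta below equilibrium) are
#'   returned as-is with a warning, never clamped.
#' @export
effective_steps_exact <- function(eta = NULL, etaEq, log_eta = NULL) {
  if (!is.numeric(etaEq) || any(etaEq <= 1))
    stop("'etaEq' must be > 1 (etaEq = 1 leaves n undefined)", call. = FALSE)
  if (is.null(log_eta)) {
    if (any(eta < 0)) stop("'eta' must be non-negative", call. = FALSE)
    log_eta <- log(eta)
  }
  n <- (log_eta - log(etaEq)) / log(etaEq)
  if (any(n < 0)) warning("fidelity below equilibrium: negative n returned",
                          call. = FALSE)
  n
}

#' Asymptotic estimate of the effective step number
#'
#' Slow-diffusion estimate `n ~ sqrt(tauD * koffW) / log(etaEq)`. Since
#' tauD scales as L^2, this gives the linear growth of proofreading power
#' with compartment size (n ~ L). Relative to the exact count obtained from
#' the closed-form fidelity, the estimate is offset by
#' `(sqrt(tauD * koffR) + log(etaEq)/2) / log(etaEq)` in the large-tauD
#' limit, a relation exercised by the test suite.
#'
#' @param koffW wrong-substrate off-rate (1/s).
#' @param tauD diffusion time scale (s); vectorized.
#' @param etaEq equilibrium fidelity (> 1).
#' @return Estimated n (dimensionless).
#' @export
effective_steps_estimate <- function(koffW, tauD, etaEq) {
  if (any(koffW <= 0) || any(tauD < 0)) stop("invalid arguments", call. = FALSE)
  if (any(etaEq <= 1)) stop("'etaEq' must be > 1", call. = FALSE)
  sqrt(tauD * koffW) / log(etaEq)
}

#' Effective thermodynamic driving force
#'
#' Dimensionless chemical-potential drop across the compartment for an
#' exponentially localized substrate: betaDeltaMu = L/lambdaS. A uniform
#' profile (`lambdaS = Inf`) carries no driving force.
#'
#' @param L compartment length (um).
#' @param lambdaS substrate localization length scale (um), possibly `Inf`.
#' @return betaDeltaMu (dimensionless, in units of kB*T).
#' @export
driving_force <- function(L, lambdaS) {
  if (any(L <= 0)) stop("'L' must be positive", call. = FALSE)
  if (any(lambdaS <= 0)) stop("'lambdaS' must be positive (possibly Inf)",
                              call. = FALSE)
  ifelse(is.infinite(lambdaS), 0, L / lambdaS)
}

#' Rough estimate of the fidelity-optimal diffusion time
#'
#' For a finite substrate localization length the fidelity is non-monotonic
#' in tauD; the optimum is approximately
#' `tauD* = tauOffR * (L/lambdaS)^2 / etaEq`, an order-of-magnitude
#' estimate that increases with tighter relative localization.
#'
#' @param etaEq equilibrium fidelity.
#' @param L compartment length (um).
#' @param lambdaS finite substrate localization length (um).
#' @param tauOffR right-substrate unbinding time 1/koffR (s).
#' @return Estimated optimal tauD (s). Order-of-magnitude only; compare
#'   with the numerical optimum from [locate_fidelity_optimum()].
#' @export
optimal_tauD_estimate <- function(etaEq, L, lambdaS, tauOffR) {
  if (any(is.infinite(lambdaS)))
    stop("no finite optimum for a uniform profile (lambdaS = Inf)",
         call. = FALSE)
  if (any(lambdaS <= 0) || any(L <= 0) || any(etaEq <= 0) || any(tauOffR <= 0))
    stop("arguments must be positive", call. = FALSE)
  tauOffR * (L / lambdaS)^2 / etaEq
}

#' Thermodynamic ceiling on fidelity enhancement
#'
#' The driving force betaDeltaMu bounds the achievable enhancement of any
#' proofreading mechanism fed by it: eta/etaEq <= exp(betaDeltaMu). The
#' spatial scheme approaches this bound up to a linear prefactor,
#' (eta/etaEq)_max ~ exp(betaDeltaMu)/betaDeltaMu, valid for
#' betaDeltaMu >~ 1.
#'
#' @param betaDeltaMu dimensionless driving force (> 0), vectorized.
#' @param log if `TRUE`, return both quantities in natural-log space.
#' @return A list with components `bound` and `achievable`.
#' @export
max_enhancement <- function(betaDeltaMu, log = FALSE) {
  if (any(betaDeltaMu <= 0)) stop("'betaDeltaMu' must be positive",
                                  call. = FALSE)
  if (log)
    list(bound = betaDeltaMu, achievable = betaDeltaMu - base::log(betaDeltaMu))
  else
    list(bound = exp(betaDeltaMu), achievable = exp(betaDeltaMu) / betaDeltaMu)
}
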