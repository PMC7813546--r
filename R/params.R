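#' Kinetic parameters of the spatial proofreading model
#'
#' Bundles the rate constants of the enzyme-substrate reaction-diffusion
#' system. Units follow the 1D line-density convention of the package:
#' lengths in micrometres, times in seconds, substrate amounts in molecules,
#' densities in molecules per micrometre. `kon` therefore carries units of
#' um/s so that `kon * rhoS` is a first-order rate in 1/s.
#'
#' @param D enzyme diffusion constant (um^2/s).
#' @param kon substrate binding rate constant (um/s).
#' @param koffR unbinding rate of the right (cognate) substrate (1/s).
#' @param koffW unbinding rate of the wrong substrate (1/s); must satisfy
#'   `koffW >= koffR`.
#' @param r catalysis rate at the activation boundary (1/s). The default,
#'   `1e-6 * koffR`, keeps the model in the slow-catalysis regime where
#'   product formation is a passive readout.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(D = 1, kon = 1, koffR = 0.1, koffW = 1)
#' @export
kinetic_params <- function(D, kon = 1, koffR = 1, koffW = 10,
                           r = 1e-6 * koffR) {
  for (nm in c("D", "kon", "koffR", "koffW", "r")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
  }
  if (koffW < koffR)
    stop("'koffW' must be >= 'koffR' (the wrong substrate unbinds faster)",
         call. = FALSE)
  structure(list(D = D, kon = kon, koffR = koffR, koffW = koffW, r = r),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (spatial proofreading model)\n")
  cat(sprintf("  D     = %g um^2/s\n  kon   = %g um/s\n", x$D, x$kon))
  cat(sprintf("  koffR = %g 1/s\n  koffW = %g 1/s  (etaEq = %g)\n",
              x$koffR, x$koffW, x$koffW / x$koffR))
  cat(sprintf("  r     = %g 1/s\n", x$r))
  invisible(x)
}

#' Derived dimensionless groups and time scales
#'
#' Computes the quantities that control proofreading performance: the
#' diffusion time scale tauD = L^2/D, the right-substrate unbinding time
#' tauOffR = 1/koffR, the equilibrium fidelity etaEq = koffW/koffR, and the
#' dimensionless driving force betaDeltaMu = L/lambdaS (zero for a uniform,
#' infinitely extended substrate profile).
#'
#' @param kinetics a [kinetic_params] object.
#' @param L compartment length (um).
#' @param lambdaS substrate localization length scale (um); `Inf` denotes a
#'   uniform profile.
#' @return An object of class `derived_scales` with fields `tauD`,
#'   `tauOffR`, `etaEq`, `betaDeltaMu`.
#' @export
derived_scales <- function(kinetics, L, lambdaS = Inf) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("'L' must be a single positive finite length", call. = FALSE)
  if (!is.numeric(lambdaS) || length(lambdaS) != 1L || lambdaS <= 0)
    stop("'lambdaS' must be positive (possibly Inf)", call. = FALSE)
  structure(list(
    tauD = L^2 / kinetics$D,
    tauOffR = 1 / kinetics$koffR,
    etaEq = kinetics$koffW / kinetics$koffR,
    betaDeltaMu = driving_force(L, lambdaS)
  ), class = "derived_scales")
}

#' @export
print.derived_scales <- function(x, ...) {
  cat("Derived scales\n")
  cat(sprintf("  tauD        = %g s\n  tauOffR     = %g s\n", x$tauD, x$tauOffR))
  cat(sprintf("  etaEq       = %g\n  betaDeltaMu = %g\n", x$etaEq, x$betaDeltaMu))
  invisible(x)
}
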