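#' Uniform cell-centered grid on [0, L]
#'
#' Finite-volume grid used by every solver in the package. Cell centers sit
#' at x_i = (i - 1/2) * dx with dx = L/N; x = 0 is the substrate
#' localization end, x = L the activation (catalysis) end.
#'
#' @param L compartment length (um).
#' @param N number of cells (>= 16). Default 1000 gives fidelity converged
#'   to well below 0.1% in all tested regimes.
#' @return An object of class `rd_grid` with fields `L`, `N`, `dx`, `x`.
#' @export
rd_grid <- function(L, N = 1000) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("'L' must be a single positive length", call. = FALSE)
  N <- as.integer(N)
  if (is.na(N) || N < 16L) stop("'N' must be an integer >= 16", call. = FALSE)
  dx <- L / N
  structure(list(L = L, N = N, dx = dx, x = (seq_len(N) - 0.5) * dx),
            class = "rd_grid")
}

#' @export
print.rd_grid <- function(x, ...) {
  cat(sprintf("Cell-centered grid: L = %g um, N = %d cells, dx = %g um\n",
              x$L, x$N, x$dx))
  invisible(x)
}

#' Substrate concentration profile
#'
#' Builds the line density rhoS(x) of a substrate species on a grid.
#' Profiles are normalized so that the total amount integrates exactly to
#' `Ntot` (sum(rho) * dx == Ntot).
#'
#' @param grid an [rd_grid].
#' @param kind one of `"exponential"` (rho ~ exp(-x/lambdaS), the generic
#'   shape produced by cellular gradient-forming mechanisms), `"delta"`
#'   (all mass in the first cell: the lambdaS -> 0 ideal-localization
#'   limit), `"uniform"`, or `"custom"`.
#' @param lambdaS localization length scale (um) for the exponential kind;
#'   `Inf` degrades to uniform, `0` to delta. Ignored otherwise.
#' @param Ntot total substrate amount (molecules). For `"custom"` with
#'   `Ntot = NULL` the amount implied by `rho` is kept.
#' @param rho numeric vector of length `grid$N` for `kind = "custom"`
#'   (non-negative; rescaled to `Ntot` when given).
#' @return An object of class `substrate_field` with fields `kind`,
#'   `lambdaS`, `Ntot`, `rho`, `grid`.
#' @export
substrate_profile <- function(grid,
                              kind = c("exponential", "delta", "uniform",
                                       "custom"),
                              lambdaS = Inf, Ntot = 1, rho = NULL) {
  stopifnot(inherits(grid, "rd_grid"))
  kind <- match.arg(kind)
  if (kind != "custom") {
    if (is.null(Ntot) || !is.numeric(Ntot) || Ntot < 0)
      stop("'Ntot' must be a non-negative number", call. = FALSE)
  }
  if (kind == "exponential") {
    if (!is.numeric(lambdaS) || length(lambdaS) != 1L || lambdaS < 0)
      stop("'lambdaS' must be >= 0 (possibly Inf)", call. = FALSE)
    if (lambdaS == 0) kind <- "delta"
    else if (is.infinite(lambdaS)) kind <- "uniform"
  }
  rho <- switch(kind,
    exponential = {
      w <- exp(-grid$x / lambdaS)
      w * (Ntot / (sum(w) * grid$dx))
    },
    delta = c(Ntot / grid$dx, rep(0, grid$N - 1L)),
    uniform = rep(Ntot / grid$L, grid$N),
    custom = {
      if (is.null(rho) || length(rho) != grid$N || any(rho < 0))
        stop("custom profile needs a non-negative 'rho' of length grid$N",
             call. = FALSE)
      tot <- sum(rho) * grid$dx
      if (tot <= 0) stop("custom profile has zero total mass", call. = FALSE)
      if (is.null(Ntot)) Ntot <- tot else rho <- rho * (Ntot / tot)
      rho
    })
  lam <- switch(kind, exponential = lambdaS, delta = 0, uniform = Inf,
                custom = NA_real_)
  structure(list(kind = kind, lambdaS = lam, Ntot = Ntot, rho = rho,
                 grid = grid),
            class = "substrate_field")
}

#' @export
print.substrate_field <- function(x, ...) {
  cat(sprintf("Substrate profile: kind = %s, lambdaS = %g um, Ntot = %g\n",
              x$kind, x$lambdaS, x$Ntot))
  invisible(x)
}
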