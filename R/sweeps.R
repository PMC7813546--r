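# Parameter sweeps over (tauD, lambdaS, r): speed-fidelity scatter,
# Pareto-front extraction and numerical location of the fidelity optimum.
# tauD is varied through the diffusion constant D = L^2/tauD at fixed L,
# so that lambdaS/L comparisons stay meaningful; sweeps hold the total
# substrate amount Ntot fixed (not the peak density).

#' Specification of a speed-fidelity parameter sweep
#'
#' @param tauD_grid diffusion times (s), sorted ascending. Default: 25
#'   log-spaced points spanning tauD/tauOffR in [1e-2, 1e2].
#' @param lambdaS_grid localization lengths (um); may contain `0` (delta
#'   limit) and `Inf` (uniform). Default: delta, 8 log-spaced points with
#'   lambdaS/L in [0.04, 0.4], and uniform.
#' @param r_grid catalysis rates (1/s); in slow-catalysis sweeps r is a
#'   passive readout that cancels from eta and v_norm.
#' @param kinetics a [kinetic_params] (its `D` is overridden point-wise).
#' @param grid an [rd_grid].
#' @param Ntot total substrate amount per species.
#' @param rhoE uniform free-enzyme density.
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(tauD_grid = NULL, lambdaS_grid = NULL, r_grid = NULL,
                       kinetics = kinetic_params(D = 1), grid = rd_grid(1, 500),
                       Ntot = 1, rhoE = 1) {
  tauOffR <- 1 / kinetics$koffR
  if (is.null(tauD_grid))
    tauD_grid <- tauOffR * 10^seq(-2, 2, length.out = 25)
  if (is.null(lambdaS_grid))
    lambdaS_grid <- c(0, grid$L * 10^seq(log10(0.04), log10(0.4),
                                         length.out = 8), Inf)
  if (is.null(r_grid)) r_grid <- kinetics$r
  for (nm in c("tauD_grid", "lambdaS_grid", "r_grid")) {
    v <- get(nm)
    if (length(v) == 0 || is.unsorted(v))
      stop("'", nm, "' must be non-empty and sorted ascending", call. = FALSE)
  }
  structure(list(tauD_grid = tauD_grid, lambdaS_grid = lambdaS_grid,
                 r_grid = r_grid, kinetics = kinetics, grid = grid,
                 Ntot = Ntot, rhoE = rhoE),
            class = "sweep_spec")
}

.solve_point <- function(spec, tauD, lambdaS, r) {
  g <- spec$grid
  kin <- spec$kinetics
  kin$D <- g$L^2 / tauD
  kin$r <- r
  sub <- substrate_profile(g, "exponential", lambdaS = lambdaS,
                           Ntot = spec$Ntot)
  prof <- solve_linear_steady_state(g, kin, sub, sub, rhoE = spec$rhoE)
  sf <- compute_speed_fidelity(prof)
  if (sub$kind == "delta") {
    P <- Inf; cpb <- Inf           # a true delta gradient is infinitely costly
  } else {
    th <- thermo_summary(prof)
    P <- th$P; cpb <- th$cost_per_binding
  }
  list(sf = sf, P = P, cpb = cpb)
}

#' Run a (tauD x lambdaS x r) sweep
#'
#' One linearized steady-state solve per grid point; per-point failures are
#' caught, flagged and reported without aborting the sweep.
#'
#' @param spec a [sweep_spec].
#' @return data.frame with one row per point: `tauD`, `lambdaS`, `r`,
#'   `v_norm`, `eta`, `n_eff`, `P`, `cost_per_binding`, `flag` (empty
#'   string, or the solver error/warning message).
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  pts <- expand.grid(tauD = spec$tauD_grid, lambdaS = spec$lambdaS_grid,
                     r = spec$r_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    flag <- ""
    res <- withCallingHandlers(
      tryCatch(.solve_point(spec, p$tauD, p$lambdaS, p$r),
               error = function(e) { flag <<- conditionMessage(e); NULL }),
      warning = function(w) {
        flag <<- conditionMessage(w); invokeRestart("muffleWarning")
      })
    if (is.null(res))
      data.frame(tauD = p$tauD, lambdaS = p$lambdaS, r = p$r,
                 v_norm = NA_real_, eta = NA_real_, n_eff = NA_real_,
                 P = NA_real_, cost_per_binding = NA_real_, flag = flag)
    else
      data.frame(tauD = p$tauD, lambdaS = p$lambdaS, r = p$r,
                 v_norm = res$sf$v_norm, eta = res$sf$eta,
                 n_eff = res$sf$n_eff, P = res$P,
                 cost_per_binding = res$cpb, flag = flag)
  })
  do.call(rbind, rows)
}

#' Pareto-optimal speed-fidelity front
#'
#' Non-dominated subset of (v_norm, eta) points under joint maximization.
#' A point is kept unless some other point is at least as good in both
#' coordinates and strictly better in one; exact ties are kept. The front
#' is returned sorted by decreasing v_norm (hence non-decreasing eta) and
#' is invariant under duplication and permutation of the input.
#'
#' @param points data.frame with columns `v_norm` and `eta` (extra columns
#'   are carried along as provenance).
#' @return The non-dominated rows, class `pareto_front`.
#' @export
pareto_front <- function(points) {
  if (!is.data.frame(points) || !all(c("v_norm", "eta") %in% names(points)))
    stop("'points' needs columns 'v_norm' and 'eta'", call. = FALSE)
  pts <- points[is.finite(points$v_norm) & is.finite(points$eta), ,
                drop = FALSE]
  if (nrow(pts) == 0) stop("no points with finite coordinates", call. = FALSE)
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    dom <- pts$v_norm >= pts$v_norm[i] & pts$eta >= pts$eta[i] &
      (pts$v_norm > pts$v_norm[i] | pts$eta > pts$eta[i])
    !any(dom)
  }, logical(1))
  front <- pts[keep, , drop = FALSE]
  front <- front[order(-front$v_norm, front$eta), , drop = FALSE]
  rownames(front) <- NULL
  class(front) <- c("pareto_front", "data.frame")
  front
}

#' Numerically locate the fidelity optimum over the diffusion time
#'
#' For a finite localization length the fidelity eta(tauD) rises (more
#' proofreading rounds) and eventually falls again (complex profiles relax
#' onto the non-discriminating substrate profile). This routine brackets
#' the maximum on a coarse log grid and refines it by golden-section search
#' to a relative tauD tolerance of 1e-3. If the coarse maximum sits on the
#' grid edge the range is extended once (by two decades each side) and the
#' result flagged.
#'
#' @param lambdaS finite substrate localization length (um).
#' @param scenario list with `grid`, `kinetics`, `Ntot`, `rhoE` (as in
#'   [cost_and_fidelity_curve()]).
#' @param tauD_range initial search range (s); default
#'   `[1e-2, 1e2] * tauOffR`.
#' @param coarse_n coarse grid size (default 25).
#' @param rel_tol relative tauD tolerance of the golden-section refinement.
#' @return list(tauD_star, eta_max, edge) where `edge` is TRUE when the
#'   maximum remained on the boundary after one extension (the monotone,
#'   ideal-localization-like regime).
#' @export
locate_fidelity_optimum <- function(lambdaS, scenario, tauD_range = NULL,
                                    coarse_n = 25, rel_tol = 1e-3) {
  if (!is.finite(lambdaS) || lambdaS <= 0)
    stop("'lambdaS' must be finite and positive", call. = FALSE)
  g <- scenario$grid
  kin <- scenario$kinetics
  if (is.null(tauD_range)) tauD_range <- c(1e-2, 1e2) / kin$koffR
  sub <- substrate_profile(g, "exponential", lambdaS = lambdaS,
                           Ntot = scenario$Ntot)
  log_eta <- function(ltau) {
    kin$D <- g$L^2 / exp(ltau)
    prof <- solve_linear_steady_state(g, kin, sub, sub, rhoE = scenario$rhoE)
    log(prof$rhoER[g$N] / prof$rhoEW[g$N])
  }
  coarse_max <- function(rng) {
    lt <- seq(log(rng[1]), log(rng[2]), length.out = coarse_n)
    vals <- vapply(lt, log_eta, numeric(1))
    list(lt = lt, vals = vals, i = which.max(vals))
  }
  cm <- coarse_max(tauD_range)
  edge <- FALSE
  if (cm$i %in% c(1L, coarse_n)) {
    tauD_range <- c(tauD_range[1] * 1e-2, tauD_range[2] * 1e2)
    cm <- coarse_max(tauD_range)
    if (cm$i %in% c(1L, coarse_n)) edge <- TRUE
  }
  if (edge) {
    return(list(tauD_star = exp(cm$lt[cm$i]), eta_max = exp(cm$vals[cm$i]),
                edge = TRUE))
  }
  # golden-section on the bracketing interval in log tauD
  lo <- cm$lt[cm$i - 1L]; hi <- cm$lt[cm$i + 1L]
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- log_eta(c1); f2 <- log_eta(c2)
  while ((b - a) > rel_tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- log_eta(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- log_eta(c1)
    }
  }
  lt_star <- (a + b) / 2
  list(tauD_star = exp(lt_star), eta_max = exp(log_eta(lt_star)),
       edge = FALSE)
}
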