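# Preset pipelines regenerating the package's reference figures' data:
# fidelity vs diffusion time (ideal localization), the speed-fidelity
# trade-off sweep with Pareto front, the power-fidelity curves, and the
# kinase/phosphatase activity scan. Output is plain CSV (12 significant
# digits, byte-stable across runs) plus a JSON metadata sidecar.

.write_csv12 <- function(df, path) {
  fmt <- function(v) {
    if (is.numeric(v)) sprintf("%.12g", v) else as.character(v)
  }
  body <- do.call(paste, c(lapply(df, fmt), sep = ","))
  writeLines(c(paste(names(df), collapse = ","), body), path)
  invisible(path)
}

.write_meta <- function(outdir, preset, params) {
  meta <- list(preset = preset,
               package = "spatialproof",
               version = as.character(utils::packageVersion("spatialproof")),
               parameters = params)
  jsonlite::write_json(meta, file.path(outdir, paste0(preset, "_meta.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.preset_fig2 <- function(outdir, N = 500) {
  g <- rd_grid(1, N)
  tau_grid <- 10^seq(-2, 2, length.out = 41)
  files <- character()
  for (ratio in c(10, 100)) {
    kin0 <- kinetic_params(D = 1, koffR = 1, koffW = ratio)
    sub <- substrate_profile(g, "delta", Ntot = 1)
    eta <- vapply(tau_grid, function(tauD) {
      kin <- kin0; kin$D <- g$L^2 / tauD
      prof <- solve_linear_steady_state(g, kin, sub, sub)
      prof$rhoER[g$N] / prof$rhoEW[g$N]
    }, numeric(1))
    df <- data.frame(tauD_over_tauOffR = tau_grid,
                     eta_over_etaEq = eta / ratio)
    f <- file.path(outdir, sprintf("fig2_etaW%d.csv", ratio))
    .write_csv12(df, f)
    files <- c(files, f)
  }
  .write_meta(outdir, "fig2", list(koffR = 1, koffW = c(10, 100),
                                   grid_N = N, substrate = "delta"))
  files
}

.preset_fig3 <- function(outdir, N = 400) {
  spec <- sweep_spec(kinetics = kinetic_params(D = 1),
                     grid = rd_grid(1, N))
  tab <- run_sweep(spec)
  f1 <- file.path(outdir, "fig3_sweep.csv")
  .write_csv12(tab, f1)
  front <- pareto_front(tab)
  f2 <- file.path(outdir, "fig3_pareto.csv")
  .write_csv12(as.data.frame(front), f2)
  jsonlite::write_json(as.data.frame(front),
                       file.path(outdir, "fig3_pareto.json"),
                       digits = NA, pretty = TRUE)
  .write_meta(outdir, "fig3",
              list(etaEq = 10, grid_N = N,
                   tauD_grid = spec$tauD_grid, lambdaS_grid = spec$lambdaS_grid))
  c(f1, f2)
}

.preset_fig4 <- function(outdir, N = 500) {
  kin <- kinetic_params(D = 1)
  rows <- list()
  for (tauD in c(1, 10, 100)) {
    g <- rd_grid(1, N)
    k <- kin; k$D <- g$L^2 / tauD
    bdm <- c(10^seq(-1, log10(3 * sqrt(tauD * k$koffW)), length.out = 25))
    cur <- cost_and_fidelity_curve(
      list(grid = g, kinetics = k, Ntot = 1, rhoE = 1), bdm)
    cur$tauD <- tauD
    rows[[length(rows) + 1L]] <-
      cur[, c("tauD", "betaDeltaMu", "cost_per_binding", "eta_over_etaEq")]
  }
  df <- do.call(rbind, rows)
  f <- file.path(outdir, "fig4_cost_fidelity.csv")
  .write_csv12(df, f)
  .write_meta(outdir, "fig4", list(etaEq = 10, tauD = c(1, 10, 100),
                                   grid_N = N))
  f
}

.preset_fig5 <- function(outdir, N = 800) {
  base <- kp_params(N = N)
  activities <- 10^seq(-3, 3, length.out = 25)
  tab <- fidelity_vs_activity(base, activities)
  f1 <- file.path(outdir, "fig5_fidelity_vs_activity.csv")
  .write_csv12(tab, f1)
  prof_rows <- list()
  for (kE in c(0.1, 10, 1000)) {
    p <- base; p$kon_rhoE <- kE
    st <- solve_kp_steady_state(p)
    prof_rows[[length(prof_rows) + 1L]] <-
      data.frame(konRhoE = kE, x = st$grid$x, rhoSstar_R = st$R$a)
  }
  f2 <- file.path(outdir, "fig5_profiles.csv")
  .write_csv12(do.call(rbind, prof_rows), f2)
  .write_meta(outdir, "fig5",
              list(kp = base$kp, D = base$D, L = base$L, grid_N = N,
                   koffR = base$koffR, koffW = base$koffW,
                   lambdaS_theory = sqrt(base$D / base$kp)))
  c(f1, f2)
}

#' Regenerate the data behind a reference figure
#'
#' Runs one of the canned analysis pipelines and writes its CSV data files
#' plus a JSON metadata sidecar into `outdir`. Output is deterministic and
#' byte-stable (numbers formatted at 12 significant digits).
#'
#' \describe{
#'   \item{fig2}{fidelity vs diffusion time in the ideal-localization
#'     limit, one curve per koffW/koffR in \{10, 100\}.}
#'   \item{fig3}{speed-fidelity sweep over (tauD, lambdaS) at etaEq = 10,
#'     with the Pareto-optimal front.}
#'   \item{fig4}{cost-per-binding vs fidelity-enhancement curves while
#'     tuning the driving force, for tauD/tauOffR in \{1, 10, 100\}.}
#'   \item{fig5}{kinase/phosphatase model: fidelity vs enzyme activity and
#'     active-substrate profiles at selected activities.}
#' }
#'
#' @param name one of `"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`.
#' @param outdir output directory (created if missing).
#' @return Character vector of the CSV files written, invisibly.
#' @export
run_preset <- function(name = c("fig2", "fig3", "fig4", "fig5"),
                       outdir = ".") {
  name <- match.arg(name)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- switch(name,
                  fig2 = .preset_fig2(outdir),
                  fig3 = .preset_fig3(outdir),
                  fig4 = .preset_fig4(outdir),
                  fig5 = .preset_fig5(outdir))
  invisible(files)
}
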