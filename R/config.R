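# Run configuration: nested defaults, a minimal flat `section.key: value`
# text format (YAML-like, lossless round-trip), JSON configs, and strict
# validation. Unknown keys are rejected and every offending key is named.

.default_config <- function() {
  list(
    scenario = "default",
    verbosity = 1,
    outdir = ".",
    kinetics = list(D = 1, kon = 1, koffR = 1, koffW = 10, r = 1e-6),
    grid = list(L = 1, N = 1000),
    substrate = list(kind = "delta", lambdaS = 0, NtotR = 1, NtotW = 1),
    enzyme = list(mode = "linear", rhoE = 1, Etot = 1),
    sweep = list(tauD_min = 1e-2, tauD_max = 1e2, tauD_n = 25,
                 lambdaS_min = 0.04, lambdaS_max = 0.4, lambdaS_n = 8,
                 include_delta = TRUE, include_uniform = TRUE),
    thermo = list(tauD = 10, bdm_min = 0.1, bdm_max = 100, bdm_n = 25),
    kp = list(kp = 5, kkin = 1000, D = 1, L = 10, N = 1000,
              koffR = 0.1, koffW = 1, StotR = 1, StotW = 1,
              activity_min = 1e-3, activity_max = 1e3, activity_n = 13),
    preset = list(name = "fig2")
  )
}

.flatten_config <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(x[[nm]])) out <- c(out, .flatten_config(x[[nm]], key))
    else out[[key]] <- x[[nm]]
  }
  out
}

.unflatten_config <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) out[[parts]] <- flat[[key]]
    else out[[parts[1]]][[parts[2]]] <- flat[[key]]
  }
  out
}

.parse_scalar <- function(s) {
  s <- trimws(s)
  if (s %in% c("true", "TRUE", "True")) return(TRUE)
  if (s %in% c("false", "FALSE", "False")) return(FALSE)
  if (s %in% c("Inf", "inf", ".inf")) return(Inf)
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n)) return(n)
  gsub('^"|"$', "", s)
}

.format_scalar <- function(v) {
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.numeric(v)) return(sprintf("%.17g", v))
  as.character(v)
}

.validate_config <- function(flat) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  pos <- function(key) chk(is.numeric(flat[[key]]) && flat[[key]] > 0,
                           paste0("'", key, "' must be positive"))
  nneg <- function(key) chk(is.numeric(flat[[key]]) && flat[[key]] >= 0,
                            paste0("'", key, "' must be non-negative"))
  for (k in c("kinetics.D", "kinetics.kon", "kinetics.koffR",
              "kinetics.koffW", "kinetics.r", "grid.L", "enzyme.Etot",
              "thermo.tauD", "kp.kp", "kp.kkin", "kp.D", "kp.L",
              "kp.koffR", "kp.koffW")) pos(k)
  for (k in c("substrate.lambdaS", "substrate.NtotR", "substrate.NtotW",
              "enzyme.rhoE", "kp.StotR", "kp.StotW")) nneg(k)
  chk(flat[["kinetics.koffW"]] >= flat[["kinetics.koffR"]],
      "'kinetics.koffW' must be >= 'kinetics.koffR'")
  chk(flat[["kp.koffW"]] >= flat[["kp.koffR"]],
      "'kp.koffW' must be >= 'kp.koffR'")
  chk(flat[["grid.N"]] >= 16, "'grid.N' must be >= 16")
  chk(flat[["kp.N"]] >= 16, "'kp.N' must be >= 16")
  chk(flat[["substrate.kind"]] %in% c("exponential", "delta", "uniform"),
      "'substrate.kind' must be exponential, delta or uniform")
  chk(flat[["enzyme.mode"]] %in% c("linear", "nonlinear"),
      "'enzyme.mode' must be linear or nonlinear")
  chk(flat[["preset.name"]] %in% c("fig2", "fig3", "fig4", "fig5"),
      "'preset.name' must be one of fig2, fig3, fig4, fig5")
  chk(flat[["verbosity"]] %in% 0:2, "'verbosity' must be 0, 1 or 2")
  errs
}

#' Load a run configuration
#'
#' Reads a flat `section.key: value` text file (comments with `#`, blank
#' lines ignored) or a JSON file (extension `.json`), fills unset keys with
#' the documented defaults, rejects unknown keys, and validates every field
#' (all violations are reported together). An empty or missing-path call
#' returns the full default configuration: the delta-localized etaEq = 10
#' scenario with a tauD/tauOffR log grid.
#'
#' @param path path to a config file, or `NULL` for pure defaults.
#' @return Object of class `run_config` (a named nested list).
#' @seealso [dump_config()] for the lossless inverse.
#' @export
load_config <- function(path = NULL) {
  flat <- .flatten_config(.default_config())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      .flatten_config(jsonlite::read_json(path, simplifyVector = TRUE))
    } else {
      lines <- readLines(path, warn = FALSE)
      lines <- sub("#.*$", "", lines)
      lines <- trimws(lines)
      lines <- lines[nzchar(lines)]
      kv <- list()
      for (ln in lines) {
        m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
        if (length(m) != 3L)
          stop("unparseable config line: '", ln, "'", call. = FALSE)
        kv[[m[2]]] <- .parse_scalar(m[3])
      }
      kv
    }
    unknown <- setdiff(names(user), names(flat))
    if (length(unknown) > 0)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (k in names(user)) {
      if (is.numeric(flat[[k]]) && !is.numeric(user[[k]]))
        stop("config key '", k, "' must be numeric", call. = FALSE)
      flat[[k]] <- user[[k]]
    }
  }
  errs <- .validate_config(flat)
  if (length(errs) > 0)
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  structure(.unflatten_config(flat), class = "run_config")
}

#' Write a configuration to disk
#'
#' Serializes a `run_config` as flat `section.key: value` lines with full
#' numeric precision; `load_config(dump_config(cfg, path))` reproduces
#' `cfg` exactly.
#'
#' @param config a `run_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- .flatten_config(config)
  lines <- vapply(names(flat),
                  function(k) paste0(k, ": ", .format_scalar(flat[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  flat <- .flatten_config(x)
  cat("Run configuration\n")
  for (k in names(flat)) cat("  ", k, ": ", .format_scalar(flat[[k]]), "\n",
                             sep = "")
  invisible(x)
}
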