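## Scenarios, configuration files and result serialization: the
## operational shell around the model.

#' Bundle a scenario
#'
#' A scenario ties together a parameter set, a circuit variant, a cell
#' geometry and simulation settings under a name, with a free-text note
#' on what it represents.
#'
#' @param name Scenario name.
#' @param params An [xap_params()] object.
#' @param variant A [circuit_variant()].
#' @param geom A [cell_geometry()].
#' @param horizon_s Simulated horizon in seconds.
#' @param n_runs Ensemble size.
#' @param algorithm `"hybrid"` or `"direct"`.
#' @param base_seed Default RNG seed base.
#' @param init `"zero"` (all counts zero) or `"upper"` (counts of the
#'   upper stable fixed point).
#' @param gamma_p Protein decay rate (1/s) linking tau to seconds.
#' @param note Free-text provenance note.
#' @return An object of class `xap_scenario`.
#' @export
xap_scenario <- function(name, params = xap_params(),
                         variant = circuit_variant(),
                         geom = cell_geometry(),
                         horizon_s = 1e6, n_runs = 100,
                         algorithm = c("hybrid", "direct"),
                         base_seed = 1, init = c("zero", "upper"),
                         gamma_p = 5e-4, note = "") {
  algorithm <- match.arg(algorithm)
  init <- match.arg(init)
  stopifnot(is.character(name), nchar(name) > 0,
            inherits(params, "xap_params"),
            inherits(variant, "circuit_variant"),
            inherits(geom, "cell_geometry"),
            horizon_s > 0, n_runs >= 1, gamma_p > 0)
  structure(list(name = name, params = params, variant = variant,
                 geom = geom, horizon_s = horizon_s, n_runs = n_runs,
                 algorithm = algorithm, base_seed = base_seed,
                 init = init, gamma_p = gamma_p, note = note),
            class = "xap_scenario")
}

#' @export
print.xap_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': c_a = %g, horizon = %g s, %d runs (%s, init %s)\n",
              x$name, x$params$c_a, x$horizon_s, x$n_runs, x$algorithm,
              x$init))
  if (nchar(x$note)) cat("  ", x$note, "\n")
  invisible(x)
}

#' Bundled reference scenarios
#'
#' The named scenarios exercised throughout the package: the bistable
#' reference configuration, the monostable low/high extracellular
#' concentrations, the transporter/enzyme ablations, the reduced
#' binding-site variants, the three ensemble concentrations used for
#' the bimodality study, the adaptation-time scenario and the
#' bifurcation/hysteresis grid.
#'
#' @return A named list of [xap_scenario()] objects; the `fig11` entry
#'   additionally carries the `c_grid` attribute for the hysteresis
#'   protocol.
#' @export
#' @examples
#' names(fixture_scenarios())
#' fixture_scenarios()$fig9b$params$c_a  # 18.5
fixture_scenarios <- function() {
  base <- xap_params()
  sc <- list(
    fig5_bistable = xap_scenario("fig5_bistable", base,
      note = "reference bistable configuration, c_a = 13"),
    fig6a = xap_scenario("fig6a", update_params(base, c_a = 7),
      note = "monostable low expression, c_a = 7"),
    fig6b = xap_scenario("fig6b", update_params(base, c_a = 40),
      note = "monostable high expression, c_a = 40"),
    fig7a = xap_scenario("fig7a", base,
      variant = circuit_variant(xapA_removed = TRUE),
      note = "degradation enzyme removed; bistability retained"),
    fig7b = xap_scenario("fig7b", base,
      variant = circuit_variant(xapB_removed = TRUE),
      note = "transporter removed; positive feedback lost, monostable"),
    fig8a = xap_scenario("fig8a",
      update_params(base, rho_m = 0.07 * base$gamma_mp / base$rho_p,
                    c_a = 6),
      variant = circuit_variant(inducer_sites = 1),
      note = "one inducer site per dimer; rho = 0.07, c_a = 6; bistable"),
    fig8b = xap_scenario("fig8b",
      update_params(base, rho_m = 0.13 * base$gamma_mp / base$rho_p,
                    c_a = 3),
      variant = circuit_variant(promoter_sites = 1),
      note = "one promoter site; rho = 0.13, c_a = 3; bistable"),
    fig8c = xap_scenario("fig8c",
      update_params(base, rho_m = 0.1 * base$gamma_mp / base$rho_p,
                    XapR_R = 5),
      variant = circuit_variant(inducer_sites = 1, promoter_sites = 1),
      note = "no cooperativity anywhere; rho = 0.1, XapR_R = 5; monostable"),
    fig9a = xap_scenario("fig9a", update_params(base, c_a = 12),
      horizon_s = 1e6, n_runs = 5000,
      note = "ensemble from zero counts; unimodal low expression"),
    fig9b = xap_scenario("fig9b", update_params(base, c_a = 18.5),
      horizon_s = 1e6, n_runs = 5000,
      note = "ensemble from zero counts; bimodal"),
    fig9c = xap_scenario("fig9c", update_params(base, c_a = 25),
      horizon_s = 1e6, n_runs = 5000,
      note = "ensemble from zero counts; unimodal high expression"),
    fig10 = xap_scenario("fig10", update_params(base, c_a = 25),
      horizon_s = 5e5, n_runs = 1000,
      note = "adaptation times: first passage to 90% of the upper fixed point"),
    fig11 = xap_scenario("fig11", base, horizon_s = 1e6, n_runs = 5000,
      note = "bifurcation diagram with dual-initialization hysteresis")
  )
  attr(sc$fig11, "c_grid") <- c(5, 7, 9, 11, 12, 13, 15, 16.5, 18.5,
                                20, 21.5, 23, 25, 30, 40)
  sc
}

## ---------------------------------------------------------------------------
## Config loading

.SCENARIO_KEYS <- c("name", "horizon_s", "n_runs", "algorithm", "base_seed",
                    "init", "gamma_p", "note", "volume", "K_a_molar")
.VARIANT_KEYS <- c("xapA_removed", "xapB_removed", "promoter_sites",
                   "inducer_sites", "deps_coop_override", "active_policy")

#' Load a scenario from a config file
#'
#' Reads a YAML or JSON config and builds a validated scenario.  All
#' keys are optional; absent keys take the canonical defaults (so an
#' empty config is the bistable reference scenario).  Recognized keys:
#' the sixteen parameter names of [xap_params()] at the top level or
#' under `params:`, variant flags under `variant:`, and scenario
#' settings (`name`, `horizon_s`, `n_runs`, `algorithm`, `base_seed`,
#' `init`, `gamma_p`, `note`, `volume`, `K_a_molar`).  Unknown keys are
#' an error, and all schema violations are reported together.
#'
#' @param path Config file path.
#' @return An [xap_scenario()] object.
#' @export
load_config <- function(path) {
  cfg <- .read_flat_config(path)
  errs <- character(0)
  par_kv <- cfg$params %||% list()
  var_kv <- cfg$variant %||% list()
  top <- cfg[setdiff(names(cfg), c("params", "variant"))]
  ## top-level parameter keys are allowed for convenience
  par_top <- top[intersect(names(top), .NONDIM_FIELDS)]
  par_kv <- modifyList(par_kv, par_top)
  rest <- top[setdiff(names(top), .NONDIM_FIELDS)]
  unknown <- setdiff(names(rest), .SCENARIO_KEYS)
  if (length(unknown) > 0)
    errs <- c(errs, paste0("unknown key(s): ",
                           paste(unknown, collapse = ", ")))
  bad_par <- setdiff(names(par_kv), .NONDIM_FIELDS)
  if (length(bad_par) > 0)
    errs <- c(errs, paste0("unknown parameter key(s): ",
                           paste(bad_par, collapse = ", ")))
  bad_var <- setdiff(names(var_kv), .VARIANT_KEYS)
  if (length(bad_var) > 0)
    errs <- c(errs, paste0("unknown variant key(s): ",
                           paste(bad_var, collapse = ", ")))
  params <- tryCatch(
    do.call(xap_params, par_kv[intersect(names(par_kv), .NONDIM_FIELDS)]),
    error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
  variant <- tryCatch(
    do.call(circuit_variant, var_kv[intersect(names(var_kv), .VARIANT_KEYS)]),
    error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
  geom <- tryCatch(
    cell_geometry(volume = rest$volume %||% 1e-15,
                  K_a = rest$K_a_molar %||% 5e-5),
    error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
  if (length(errs) > 0)
    stop("invalid config '", path, "':\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  xap_scenario(
    name = rest$name %||% tools::file_path_sans_ext(basename(path)),
    params = params, variant = variant, geom = geom,
    horizon_s = rest$horizon_s %||% 1e6,
    n_runs = rest$n_runs %||% 100,
    algorithm = rest$algorithm %||% "hybrid",
    base_seed = rest$base_seed %||% 1,
    init = rest$init %||% "zero",
    gamma_p = rest$gamma_p %||% 5e-4,
    note = rest$note %||% ""
  )
}

#' Serialize a scenario to a config file
#'
#' Inverse of [load_config()]: writes every numeric field so that a
#' reload reproduces the scenario exactly.
#'
#' @param scenario An [xap_scenario()].
#' @param path Output path (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "xap_scenario"))
  v <- scenario$variant
  cfg <- list(
    name = scenario$name,
    params = unclass(scenario$params)[.NONDIM_FIELDS],
    variant = list(xapA_removed = v$xapA_removed,
                   xapB_removed = v$xapB_removed,
                   promoter_sites = v$promoter_sites,
                   inducer_sites = v$inducer_sites,
                   active_policy = v$active_policy),
    horizon_s = scenario$horizon_s, n_runs = scenario$n_runs,
    algorithm = scenario$algorithm, base_seed = scenario$base_seed,
    init = scenario$init, gamma_p = scenario$gamma_p,
    note = scenario$note,
    volume = scenario$geom$volume, K_a_molar = scenario$geom$K_a
  )
  if (!is.null(v$deps_coop_override))
    cfg$variant$deps_coop_override <- v$deps_coop_override
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(cfg, path, precision = 17L)
  else if (ext == "json")
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported config extension: '", ext, "'")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Result writing

#' Write result tables with a hash manifest
#'
#' Writes each element of `outputs` into `directory` (data frames as
#' CSV, everything else as JSON) together with a `manifest.json` listing
#' file names, MD5 hashes and the run context (scenario name, seeds,
#' package version, timestamp).
#'
#' @param outputs Named list of results (data frames or lists).
#' @param directory Output directory (created if absent).
#' @param scenario Optional [xap_scenario()] recorded in the manifest.
#' @param seeds Optional seed vector recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(outputs, directory, scenario = NULL, seeds = NULL) {
  stopifnot(is.list(outputs), length(names(outputs)) == length(outputs),
            all(nchar(names(outputs)) > 0))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(outputs)) {
    obj <- outputs[[nm]]
    if (is.data.frame(obj)) {
      f <- file.path(directory, paste0(nm, ".csv"))
      write.csv(obj, f, row.names = FALSE)
    } else {
      f <- file.path(directory, paste0(nm, ".json"))
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
    }
    files <- c(files, f)
  }
  manifest <- list(
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))),
    scenario = if (!is.null(scenario)) scenario$name else NULL,
    seeds = seeds,
    package_version = as.character(utils::packageVersion("xapswitch")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
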