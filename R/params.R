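## Parameter containers: nondimensional (canonical) and dimensional forms.

## canonical field order for the nondimensional parameter set
.NONDIM_FIELDS <- c(
  "rho_m", "gamma_mp", "rho_p", "XapR_R", "c_a",
  "k_beta_i", "k_beta_e", "k_alpha", "k_eta", "xi",
  "K_beta_i", "K_beta_e", "K_chiA", "K_IA", "deps_x", "deps_coop"
)

## fields that are energies (in units of k_B T) and may take any finite value
.ENERGY_FIELDS <- c("deps_x", "deps_coop")

#' Nondimensional parameter set of the transporter-feedback switch
#'
#' Constructs the canonical nondimensional parameter set of the model.
#' Time is measured in units of the inverse protein decay rate
#' (1/gamma_p) and all concentrations in units of the XapA Michaelis
#' constant K_a, except the transcription factor, which is measured in
#' units of its promoter dissociation constant.  Defaults are the
#' canonical reference values of the model (the "Table 1" scenario);
#' calling `xap_params()` with no arguments therefore returns the
#' bistable reference configuration.
#'
#' @param rho_m Nondimensional transcription strength.  In dimensional
#'   terms `r_m / (gamma_p * K_a) * P / (K_P + P)`; the polymerase
#'   saturation factor is folded in, so the nondimensional model never
#'   carries the polymerase concentration separately.
#' @param gamma_mp Ratio of mRNA to protein decay rates, `gamma_m / gamma_p`.
#' @param rho_p Nondimensional translation rate, `r_p / gamma_p`.
#' @param XapR_R Total transcription-factor dimer concentration in units
#'   of its promoter dissociation constant.
#' @param c_a Extracellular inducer (xanthosine) concentration in units
#'   of K_a.
#' @param k_beta_i,k_beta_e XapB import/export turnover rates over gamma_p.
#' @param K_beta_i,K_beta_e XapB import/export Michaelis constants over K_a.
#' @param k_alpha XapA (degradation enzyme) turnover rate over gamma_p.
#' @param k_eta Non-specific (Nup) uptake rate over gamma_p.
#' @param xi Efflux-to-influx asymmetry of the non-specific transport.
#' @param K_chiA Dissociation constant of the inducer to the *active*
#'   transcription factor, in units of K_a.
#' @param K_IA Ratio of inactive-state to active-state inducer
#'   dissociation constants; values above 1 make the ligand an activator.
#' @param deps_x Free-energy gap between the inactive and active
#'   conformations of the transcription factor, in k_B T.  Positive
#'   values favour the inactive state in the absence of inducer.
#' @param deps_coop Favourable interaction free energy between the two
#'   promoter-bound transcription-factor dimers, in k_B T.  The
#'   doubly-occupied promoter states carry a statistical-weight factor
#'   `exp(deps_coop)`; `deps_coop = 0` removes promoter cooperativity.
#'
#' @return An object of class `xap_params`: a named list of the sixteen
#'   parameters plus the derived lumped expression strength
#'   `rho = rho_m * rho_p / gamma_mp`.
#' @seealso [dimensional_params()], [nondimensionalize()], [table1_params()]
#' @export
#' @examples
#' p <- xap_params()          # bistable reference scenario (c_a = 13)
#' p$rho                      # lumped expression strength, 0.01
#' p7 <- xap_params(c_a = 7)  # monostable low-expression scenario
xap_params <- function(rho_m = 1e-3, gamma_mp = 1e1, rho_p = 1e2,
                       XapR_R = 1, c_a = 13,
                       k_beta_i = 5e4, k_beta_e = 1e3, k_alpha = 1e2,
                       k_eta = 0.5, xi = 0.8,
                       K_beta_i = 1e1, K_beta_e = 1e2,
                       K_chiA = 1e2, K_IA = 1e2,
                       deps_x = 5, deps_coop = 5) {
  p <- mget(.NONDIM_FIELDS)
  validate_params(p)
  p$rho <- p$rho_m * p$rho_p / p$gamma_mp
  structure(p, class = "xap_params")
}

#' Canonical reference parameter set
#'
#' Frozen factory for the canonical reference configuration of the
#' model (all defaults of [xap_params()], `c_a = 13`), the scenario in
#' which the system is bistable with a low-expression and a
#' high-expression stable fixed point.
#'
#' @return An `xap_params` object.
#' @export
table1_params <- function() xap_params()

validate_params <- function(p) {
  missing <- setdiff(.NONDIM_FIELDS, names(p))
  if (length(missing) > 0L)
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  errs <- character(0)
  for (f in .NONDIM_FIELDS) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      errs <- c(errs, sprintf("'%s' must be a single finite number", f))
    } else if (!(f %in% .ENERGY_FIELDS) && v <= 0) {
      errs <- c(errs, sprintf("'%s' must be strictly positive (got %g)", f, v))
    }
  }
  if (length(errs) > 0L)
    stop("invalid parameter set:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced and the
#' derived `rho` recomputed; validation is re-run.
#'
#' @param params An `xap_params` object.
#' @param ... Named scalar replacements, e.g. `c_a = 18.5`.
#' @return An `xap_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "xap_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), .NONDIM_FIELDS)
  if (length(unknown) > 0L)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  do.call(xap_params, modifyList(unclass(params)[.NONDIM_FIELDS], repl))
}

#' @export
print.xap_params <- function(x, ...) {
  cat("Nondimensional switch parameters (time in 1/gamma_p, conc. in K_a)\n")
  vals <- unlist(unclass(x)[.NONDIM_FIELDS])
  print(vals)
  cat(sprintf("derived rho = rho_m*rho_p/gamma_mp = %g\n", x$rho))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Dimensional parameters

.DIM_FIELDS <- c("r_m", "gamma_m", "r_p", "gamma_p", "K_XapR", "K_P",
                 "P_conc", "K_xA", "K_xI", "dE_x", "dE_coop", "XapR_tot",
                 "k_a", "K_a", "k_bi", "K_bi", "k_be", "K_be", "k_nup",
                 "xi", "c")

#' Dimensional parameter set
#'
#' The dimensional twin of [xap_params()].  Units: rates in 1/s (the
#' transcription rate `r_m` in 1/(M s) because it absorbs the gene copy
#' number), concentrations and dissociation constants in molar, energies
#' in k_B T.  The default values reproduce the canonical nondimensional
#' set under `gamma_p = 5e-4` / s and `K_a = 5e-5` M when passed through
#' [nondimensionalize()].
#'
#' @param r_m Transcription rate, 1/(M s).
#' @param gamma_m,gamma_p mRNA and protein decay rates, 1/s.
#' @param r_p Translation rate, 1/s.
#' @param K_XapR,K_P Promoter dissociation constants of the
#'   transcription factor and of polymerase, M.
#' @param P_conc Polymerase concentration, M.
#' @param K_xA,K_xI Inducer dissociation constants to the active and
#'   inactive transcription factor, M.
#' @param dE_x Inactive-active conformational energy gap, k_B T.
#' @param dE_coop Favourable interaction energy of the two bound
#'   transcription-factor dimers, k_B T (statistical weight `exp(dE_coop)`
#'   on double occupancy).
#' @param XapR_tot Total transcription-factor dimer concentration, M.
#' @param k_a,K_a Turnover rate (1/s) and Michaelis constant (M) of the
#'   degradation enzyme.
#' @param k_bi,K_bi,k_be,K_be Import/export turnover rates (1/s) and
#'   Michaelis constants (M) of the transporter.
#' @param k_nup Non-specific uptake rate, 1/s.
#' @param xi Efflux-to-influx asymmetry (dimensionless).
#' @param c Extracellular inducer concentration, M.
#' @return An object of class `xap_dimensional_params`.
#' @export
#' @examples
#' dp <- dimensional_params()
#' np <- nondimensionalize(dp)
#' all.equal(np$c_a, 13)
dimensional_params <- function(r_m = 1e-3 * 5e-4 * 5e-5 / 0.5,
                               gamma_m = 5e-3, r_p = 5e-2, gamma_p = 5e-4,
                               K_XapR = 1e-8, K_P = 1e-6, P_conc = 1e-6,
                               K_xA = 5e-3, K_xI = 5e-1,
                               dE_x = 5, dE_coop = 5,
                               XapR_tot = 1e-8,
                               k_a = 5e-2, K_a = 5e-5,
                               k_bi = 25, K_bi = 5e-4,
                               k_be = 0.5, K_be = 5e-3,
                               k_nup = 2.5e-4, xi = 0.8, c = 6.5e-4) {
  p <- mget(.DIM_FIELDS)
  errs <- character(0)
  for (f in .DIM_FIELDS) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      errs <- c(errs, sprintf("'%s' must be a single finite number", f))
    } else if (!(f %in% c("dE_x", "dE_coop", "c")) && v <= 0) {
      errs <- c(errs, sprintf("'%s' must be strictly positive (got %g)", f, v))
    } else if (f == "c" && v < 0) {
      errs <- c(errs, "'c' must be nonnegative")
    }
  }
  if (length(errs) > 0L)
    stop("invalid dimensional parameter set:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  structure(p, class = "xap_dimensional_params")
}

#' @export
print.xap_dimensional_params <- function(x, ...) {
  cat("Dimensional switch parameters (s, M, k_B T)\n")
  print(unlist(unclass(x)[.DIM_FIELDS]))
  invisible(x)
}

#' Nondimensionalize a dimensional parameter set
#'
#' Applies the canonical scaling: time by `1/gamma_p`, concentrations by
#' `K_a` (the transcription factor by `K_XapR`), and folds the
#' polymerase saturation factor `P/(K_P + P)` into the transcription
#' strength `rho_m`.
#'
#' @param dparams An `xap_dimensional_params` object.
#' @return An `xap_params` object.
#' @export
nondimensionalize <- function(dparams) {
  stopifnot(inherits(dparams, "xap_dimensional_params"))
  d <- dparams
  if (d$gamma_p <= 0 || d$K_a <= 0)
    stop("gamma_p and K_a must be strictly positive")
  pol_term <- d$P_conc / (d$K_P + d$P_conc)
  xap_params(
    rho_m    = d$r_m / (d$gamma_p * d$K_a) * pol_term,
    gamma_mp = d$gamma_m / d$gamma_p,
    rho_p    = d$r_p / d$gamma_p,
    XapR_R   = d$XapR_tot / d$K_XapR,
    c_a      = d$c / d$K_a,
    k_beta_i = d$k_bi / d$gamma_p,
    k_beta_e = d$k_be / d$gamma_p,
    k_alpha  = d$k_a / d$gamma_p,
    k_eta    = d$k_nup / d$gamma_p,
    xi       = d$xi,
    K_beta_i = d$K_bi / d$K_a,
    K_beta_e = d$K_be / d$K_a,
    K_chiA   = d$K_xA / d$K_a,
    K_IA     = d$K_xI / d$K_xA,
    deps_x   = d$dE_x,
    deps_coop = d$dE_coop
  )
}

#' Rebuild a dimensional parameter set from a nondimensional one
#'
#' Inverse of [nondimensionalize()] given the scales that the
#' nondimensional form does not carry: the protein decay rate, the
#' enzyme Michaelis constant, the transcription-factor promoter
#' dissociation constant and the polymerase saturation split
#' (`K_P` and the saturation value `pol_term`, from which the polymerase
#' concentration is reconstructed).
#'
#' @param params An `xap_params` object.
#' @param gamma_p Protein decay rate, 1/s.
#' @param K_a Enzyme Michaelis constant, M.
#' @param K_XapR Promoter dissociation constant of the transcription factor, M.
#' @param K_P Polymerase promoter dissociation constant, M.
#' @param pol_term Polymerase saturation `P/(K_P+P)`, in (0, 1).
#' @return An `xap_dimensional_params` object.
#' @export
dimensionalize <- function(params, gamma_p = 5e-4, K_a = 5e-5,
                           K_XapR = 1e-8, K_P = 1e-6, pol_term = 0.5) {
  stopifnot(inherits(params, "xap_params"))
  if (pol_term <= 0 || pol_term >= 1)
    stop("'pol_term' must lie strictly inside (0, 1)")
  p <- params
  dimensional_params(
    r_m     = p$rho_m * gamma_p * K_a / pol_term,
    gamma_m = p$gamma_mp * gamma_p,
    r_p     = p$rho_p * gamma_p,
    gamma_p = gamma_p,
    K_XapR  = K_XapR,
    K_P     = K_P,
    P_conc  = pol_term * K_P / (1 - pol_term),
    K_xA    = p$K_chiA * K_a,
    K_xI    = p$K_IA * p$K_chiA * K_a,
    dE_x    = p$deps_x,
    dE_coop = p$deps_coop,
    XapR_tot = p$XapR_R * K_XapR,
    k_a     = p$k_alpha * gamma_p,
    K_a     = K_a,
    k_bi    = p$k_beta_i * gamma_p,
    K_bi    = p$K_beta_i * K_a,
    k_be    = p$k_beta_e * gamma_p,
    K_be    = p$K_beta_e * K_a,
    k_nup   = p$k_eta * gamma_p,
    xi      = p$xi,
    c       = p$c_a * K_a
  )
}

## ---------------------------------------------------------------------------
## Flat key-value serialization (YAML / JSON by file extension)

#' Write a parameter set to a flat config file
#'
#' Serializes the sixteen nondimensional parameters as a flat key-value
#' mapping.  The format is chosen from the file extension: `.yaml`/`.yml`
#' or `.json`.
#'
#' @param params An `xap_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "xap_params"))
  kv <- unclass(params)[.NONDIM_FIELDS]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(kv, path, precision = 17L)
  } else if (ext == "json") {
    jsonlite::write_json(kv, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config extension: '", ext, "' (use yaml or json)")
  }
  invisible(path)
}

#' Read a parameter set from a flat config file
#'
#' Reads a flat key-value mapping (YAML or JSON) and merges it onto the
#' canonical defaults: keys that are absent keep their [xap_params()]
#' default, unknown keys are an error.
#'
#' @param path Config file path.
#' @return An `xap_params` object.
#' @export
read_params <- function(path) {
  kv <- .read_flat_config(path)
  unknown <- setdiff(names(kv), .NONDIM_FIELDS)
  if (length(unknown) > 0L)
    stop("unknown parameter key(s) in '", path, "': ",
         paste(unknown, collapse = ", "))
  do.call(xap_params, kv)
}

.read_flat_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  kv <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: '", ext, "' (use yaml or json)")
  }
  if (is.null(kv)) kv <- list()
  as.list(kv)
}
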