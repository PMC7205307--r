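## Structural circuit variants: transporter/enzyme removal, binding-site
## counts, cooperativity override, and the promoter-activity policy.

#' Structural circuit variant
#'
#' Describes a structural edit of the circuit.  The default variant is a
#' strict identity: it reproduces the headline model exactly.
#'
#' @param xapA_removed Remove the degradation enzyme (drops the
#'   `k_alpha` term from the inducer rate equation).
#' @param xapB_removed Remove the transporter (drops both `k_beta`
#'   terms; only non-specific transport remains).
#' @param promoter_sites Number of transcription-factor binding sites on
#'   the promoter, 1 or 2.  With one site the active-state probability
#'   becomes `r / (1 + r)` and no cooperativity factor exists.
#' @param inducer_sites Number of inducer binding sites per
#'   transcription-factor dimer, 1 or 2 (the exponents of the MWC
#'   active-fraction formula).
#' @param deps_coop_override Optional replacement for the promoter
#'   cooperativity energy (k_B T); incompatible with `promoter_sites = 1`.
#' @param active_policy Which promoter states transcribe:
#'   `"fully_occupied_only"` (default; only the doubly-bound,
#'   polymerase-bound state) or `"any_xapr_bound"` (every state with at
#'   least one bound activator transcribes at the full rate).
#' @return An object of class `circuit_variant`.
#' @export
#' @examples
#' circuit_variant()                    # headline model
#' circuit_variant(xapB_removed = TRUE) # no transporter: no positive feedback
circuit_variant <- function(xapA_removed = FALSE, xapB_removed = FALSE,
                            promoter_sites = 2, inducer_sites = 2,
                            deps_coop_override = NULL,
                            active_policy = c("fully_occupied_only",
                                              "any_xapr_bound")) {
  active_policy <- match.arg(active_policy)
  stopifnot(is.logical(xapA_removed), length(xapA_removed) == 1L,
            is.logical(xapB_removed), length(xapB_removed) == 1L)
  if (!promoter_sites %in% c(1, 2))
    stop("'promoter_sites' must be 1 or 2")
  if (!inducer_sites %in% c(1, 2))
    stop("'inducer_sites' must be 1 or 2")
  if (!is.null(deps_coop_override)) {
    if (!is.numeric(deps_coop_override) || length(deps_coop_override) != 1L ||
        !is.finite(deps_coop_override))
      stop("'deps_coop_override' must be a single finite number")
    if (promoter_sites == 1)
      stop("'deps_coop_override' is contradictory with promoter_sites = 1: ",
           "a single-site promoter has no pairwise interaction energy")
  }
  structure(list(xapA_removed = xapA_removed, xapB_removed = xapB_removed,
                 promoter_sites = as.integer(promoter_sites),
                 inducer_sites = as.integer(inducer_sites),
                 deps_coop_override = deps_coop_override,
                 active_policy = active_policy),
            class = "circuit_variant")
}

#' @export
print.circuit_variant <- function(x, ...) {
  dflt <- identical(unclass(x), unclass(circuit_variant()))
  cat("Circuit variant", if (dflt) "(headline model)" else "", "\n")
  cat(sprintf("  XapA removed: %s | XapB removed: %s\n",
              x$xapA_removed, x$xapB_removed))
  cat(sprintf("  promoter sites: %d | inducer sites per dimer: %d\n",
              x$promoter_sites, x$inducer_sites))
  cat(sprintf("  deps_coop override: %s | active policy: %s\n",
              if (is.null(x$deps_coop_override)) "none"
              else format(x$deps_coop_override), x$active_policy))
  invisible(x)
}

## effective cooperativity energy under a variant
effective_deps_coop <- function(params, variant) {
  if (!is.null(variant$deps_coop_override)) variant$deps_coop_override
  else params$deps_coop
}

.check_variant <- function(variant) {
  if (is.null(variant)) return(circuit_variant())
  if (!inherits(variant, "circuit_variant"))
    stop("'variant' must be a circuit_variant object")
  variant
}

#' Fixed-point structure across a cooperativity grid
#'
#' Runs the fixed-point search for each value of the promoter
#' cooperativity energy and reports whether bistability (three fixed
#' points) persists.
#'
#' @param params An `xap_params` object.
#' @param deps_coop_values Numeric vector of cooperativity energies (k_B T).
#' @param variant Optional base [circuit_variant()]; its
#'   `deps_coop_override` is replaced per grid value.
#' @param ... Passed on to [find_fixed_points()].
#' @return A data frame with columns `deps_coop`, `n_fixed_points`,
#'   `bistable`, and an attribute `"fixed_points"` holding the per-value
#'   fixed-point tables.
#' @export
cooperativity_sweep <- function(params, deps_coop_values, variant = NULL, ...) {
  variant <- .check_variant(variant)
  if (variant$promoter_sites == 1)
    stop("cooperativity sweep is undefined for a single-site promoter")
  fps <- lapply(deps_coop_values, function(dc) {
    v <- variant
    v$deps_coop_override <- dc
    find_fixed_points(params, variant = v, ...)
  })
  out <- data.frame(
    deps_coop = deps_coop_values,
    n_fixed_points = vapply(fps, nrow, integer(1))
  )
  out$bistable <- out$n_fixed_points == 3L
  attr(out, "fixed_points") <- fps
  out
}
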