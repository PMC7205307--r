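## Right-hand sides of the deterministic rate equations (nondimensional
## and dimensional) and the analytic Jacobian.

## per-protein net transport/degradation flux T(x_a) such that
## dx_a/dtau = T(x_a) * p_a + k_eta (c_a - xi x_a)
transport_flux <- function(x_a, params, variant = NULL) {
  variant <- .check_variant(variant)
  flux <- 0
  if (!variant$xapB_removed) {
    flux <- flux +
      params$k_beta_i * params$c_a / (params$K_beta_i + params$c_a) -
      params$k_beta_e * x_a / (params$K_beta_e + x_a)
  }
  if (!variant$xapA_removed) {
    flux <- flux - params$k_alpha * x_a / (1 + x_a)
  }
  flux
}

## d T / d x_a
transport_flux_deriv <- function(x_a, params, variant = NULL) {
  variant <- .check_variant(variant)
  d <- 0
  if (!variant$xapB_removed)
    d <- d - params$k_beta_e * params$K_beta_e / (params$K_beta_e + x_a)^2
  if (!variant$xapA_removed)
    d <- d - params$k_alpha / (1 + x_a)^2
  d
}

#' Nondimensional rate equations
#'
#' Time derivatives of the nondimensional state
#' `(m_a, p_a, x_a)` (mRNA, protein, intracellular inducer, all in units
#' of K_a; time in units of 1/gamma_p):
#' \deqn{\dot m_a = \rho_m\, p_{active}(x_a) - \gamma_{mp} m_a}
#' \deqn{\dot p_a = \rho_p\, m_a - p_a}
#' \deqn{\dot x_a = \Big(\frac{k_{\beta,i} c_a}{K_{\beta,i}+c_a}
#'   - \frac{k_{\beta,e} x_a}{K_{\beta,e}+x_a}
#'   - \frac{k_\alpha x_a}{1+x_a}\Big) p_a + k_\eta (c_a - \xi x_a)}
#' Circuit variants zero out the XapA and/or XapB terms and modify
#' `p_active`.
#'
#' @param state Numeric vector `c(m_a, p_a, x_a)`, nonnegative.
#' @param params An [xap_params()] object.
#' @param variant Optional [circuit_variant()].
#' @return Numeric vector of the three time derivatives.
#' @export
#' @examples
#' xap_rhs(c(0, 0, 0), xap_params())  # at the origin only influx acts
xap_rhs <- function(state, params, variant = NULL) {
  variant <- .check_variant(variant)
  if (length(state) != 3L || any(!is.finite(state)))
    stop("'state' must be three finite numbers (m_a, p_a, x_a)")
  if (any(state < 0))
    stop("'state' must be nonnegative")
  m <- state[[1]]; p <- state[[2]]; x <- state[[3]]
  act <- promoter_activity(x, params, variant)
  c(params$rho_m * act - params$gamma_mp * m,
    params$rho_p * m - p,
    transport_flux(x, params, variant) * p +
      params$k_eta * (params$c_a - params$xi * x))
}

#' Dimensional rate equations
#'
#' Dimensional twin of [xap_rhs()]: derivatives of the molar
#' concentrations `([m], [p], [x])` in M/s, using the instantaneous mRNA
#' concentration in the translation term.
#'
#' @param state Numeric vector `c(m, p, x)` of molar concentrations.
#' @param dparams An [dimensional_params()] object.
#' @param variant Optional [circuit_variant()].
#' @return Numeric vector of the three time derivatives, M/s.
#' @export
xap_rhs_dimensional <- function(state, dparams, variant = NULL) {
  stopifnot(inherits(dparams, "xap_dimensional_params"))
  variant <- .check_variant(variant)
  if (length(state) != 3L || any(!is.finite(state)) || any(state < 0))
    stop("'state' must be three finite nonnegative concentrations")
  d <- dparams
  m <- state[[1]]; p <- state[[2]]; x <- state[[3]]
  np <- nondimensionalize(d)
  pol_term <- d$P_conc / (d$K_P + d$P_conc)
  ## promoter activity from dimensional quantities (r in K_XapR units)
  r <- (d$XapR_tot / d$K_XapR) *
    xapr_active_fraction(x / d$K_a, np, variant)
  act <- promoter_active_probability(r, np, variant, pol_term = pol_term)
  flux <- 0
  if (!variant$xapB_removed)
    flux <- flux + d$k_bi * d$c / (d$K_bi + d$c) - d$k_be * x / (d$K_be + x)
  if (!variant$xapA_removed)
    flux <- flux - d$k_a * x / (d$K_a + x)
  c(d$r_m * act - d$gamma_m * m,
    d$r_p * m - d$gamma_p * p,
    flux * p + d$k_nup * (d$c - d$xi * x))
}

#' Analytic Jacobian of the nondimensional system
#'
#' The 3x3 matrix of partial derivatives of [xap_rhs()] with respect to
#' `(m_a, p_a, x_a)`.  The protein equation is linear, so its row is
#' `(rho_p, -1, 0)` everywhere.
#'
#' @inheritParams xap_rhs
#' @return A 3x3 numeric matrix with dimnames
#'   `c("m_a", "p_a", "x_a")`.
#' @export
xap_jacobian <- function(state, params, variant = NULL) {
  variant <- .check_variant(variant)
  if (length(state) != 3L || any(!is.finite(state)) || any(state < 0))
    stop("'state' must be three finite nonnegative numbers")
  p <- state[[2]]; x <- state[[3]]
  dact <- promoter_activity_deriv(x, params, variant)
  flux <- transport_flux(x, params, variant)
  dflux <- transport_flux_deriv(x, params, variant)
  J <- rbind(
    c(-params$gamma_mp, 0, params$rho_m * dact),
    c(params$rho_p, -1, 0),
    c(0, flux, dflux * p - params$k_eta * params$xi)
  )
  dimnames(J) <- list(c("m_a", "p_a", "x_a"), c("m_a", "p_a", "x_a"))
  J
}
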