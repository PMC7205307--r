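## Regulatory input functions: MWC induction of the transcription factor
## and the thermodynamic (statistical-weight) promoter model.

#' MWC active fraction of the transcription factor
#'
#' Fraction of transcription-factor dimers in the active conformation as
#' a function of the intracellular inducer concentration, under the
#' two-state Monod-Wyman-Changeux model with `inducer_sites` identical
#' ligand sites per dimer:
#' \deqn{f(x) = \frac{(1 + x/K_{\chi A})^n}{(1 + x/K_{\chi A})^n +
#'   e^{\Delta\epsilon_x}\,(1 + x/(K_{\chi A} K_{IA}))^n}}
#' At zero inducer the fraction collapses to the leak level
#' `1 / (1 + exp(deps_x))`; for `K_IA > 1` it increases monotonically to
#' `1 / (1 + exp(deps_x) * K_IA^-n)` at saturation.
#'
#' @param x_a Intracellular inducer concentration in units of K_a
#'   (nonnegative; vectorized).
#' @param params An [xap_params()] object (uses `K_chiA`, `K_IA`, `deps_x`).
#' @param variant Optional [circuit_variant()]; `inducer_sites` sets the
#'   exponent.
#' @return Active fraction in (0, 1), same length as `x_a`.
#' @export
#' @examples
#' p <- xap_params()
#' xapr_active_fraction(0, p)      # leak level 1/(1 + e^5)
#' xapr_active_fraction(1e6, p)    # near-saturated
xapr_active_fraction <- function(x_a, params, variant = NULL) {
  variant <- .check_variant(variant)
  if (any(!is.finite(x_a)) || any(x_a < 0))
    stop("'x_a' must be finite and nonnegative")
  for (f in c("K_chiA", "K_IA", "deps_x"))
    if (!is.finite(params[[f]])) stop("non-finite parameter: ", f)
  n <- variant$inducer_sites
  u <- x_a / params$K_chiA
  act <- (1 + u)^n
  inact <- exp(params$deps_x) * (1 + u / params$K_IA)^n
  act / (act + inact)
}

#' Thermodynamic weights of the eight promoter states
#'
#' Statistical weights of the promoter occupancy states for a promoter
#' with two activator sites and one polymerase site, with independent
#' polymerase binding.  State order: empty; activator on site 1;
#' activator on site 2; both activator sites; polymerase alone;
#' polymerase + site 1; polymerase + site 2; polymerase + both sites.
#' The doubly-occupied states carry the cooperativity factor
#' `exp(deps_coop)` (favourable interaction of the two bound dimers).
#' The partition function factorizes:
#' `sum(w) == (1 + pol_ratio) * (1 + 2 r + r^2 exp(deps_coop))`.
#'
#' @param xapr_ratio Active transcription-factor concentration over its
#'   promoter dissociation constant (nonnegative scalar).
#' @param pol_ratio Polymerase concentration over its promoter
#'   dissociation constant (nonnegative scalar).
#' @param deps_coop Pairwise interaction energy, k_B T.
#' @return Named numeric vector of eight nonnegative weights (the empty
#'   state has weight 1).
#' @export
promoter_state_weights <- function(xapr_ratio, pol_ratio, deps_coop = 5) {
  stopifnot(length(xapr_ratio) == 1L, length(pol_ratio) == 1L)
  if (!is.finite(xapr_ratio) || xapr_ratio < 0)
    stop("'xapr_ratio' must be finite and nonnegative")
  if (!is.finite(pol_ratio) || pol_ratio < 0)
    stop("'pol_ratio' must be finite and nonnegative")
  r <- xapr_ratio
  q <- pol_ratio
  coop <- exp(deps_coop)
  w <- c(empty        = 1,
         xapr_site1   = r,
         xapr_site2   = r,
         xapr_both    = r^2 * coop,
         pol          = q,
         pol_xapr1    = q * r,
         pol_xapr2    = q * r,
         pol_xapr_both = q * r^2 * coop)
  w
}

#' Probability that the promoter is transcriptionally active
#'
#' Under the default policy only the fully occupied state (both
#' activator sites and polymerase) transcribes, giving
#' \deqn{p_{active} = \mathrm{pol\_term} \cdot
#'   \frac{r^2 e^{\Delta\epsilon_{coop}}}{1 + 2r + r^2 e^{\Delta\epsilon_{coop}}}}
#' with `r` the active transcription factor over its promoter
#' dissociation constant.  In nondimensional use `pol_term` is 1 (the
#' polymerase saturation factor is folded into `rho_m`); dimensional
#' callers pass it explicitly.  Variants: a single-site promoter gives
#' `r / (1 + r)`; the `"any_xapr_bound"` policy counts every
#' activator-bound state as transcribing at the full rate.
#'
#' @param xapr_active Active transcription-factor concentration in units
#'   of its promoter dissociation constant (nonnegative; vectorized).
#' @param params An [xap_params()] object (uses `deps_coop`).
#' @param variant Optional [circuit_variant()].
#' @param pol_term Polymerase saturation factor in (0, 1]; 1 in
#'   nondimensional mode.
#' @return Probability in `[0, pol_term)`, same length as `xapr_active`.
#' @export
#' @examples
#' p <- xap_params()
#' promoter_active_probability(0, p)        # 0: no activator, no transcription
#' promoter_active_probability(1e9, p)      # saturates at pol_term = 1
promoter_active_probability <- function(xapr_active, params, variant = NULL,
                                        pol_term = 1) {
  variant <- .check_variant(variant)
  if (any(!is.finite(xapr_active)) || any(xapr_active < 0))
    stop("'xapr_active' must be finite and nonnegative")
  if (!is.finite(pol_term) || pol_term <= 0 || pol_term > 1)
    stop("'pol_term' must lie in (0, 1]")
  r <- xapr_active
  if (variant$promoter_sites == 1L) {
    occ <- r / (1 + r)
  } else {
    coop <- exp(effective_deps_coop(params, variant))
    z <- 1 + 2 * r + r^2 * coop
    occ <- switch(variant$active_policy,
      fully_occupied_only = r^2 * coop / z,
      any_xapr_bound      = (2 * r + r^2 * coop) / z,
      stop("invalid active policy: ", variant$active_policy))
  }
  pol_term * occ
}

#' Promoter activity as a function of inducer concentration
#'
#' Convenience composition of [xapr_active_fraction()] and
#' [promoter_active_probability()]: the probability of the transcribing
#' promoter state at intracellular inducer concentration `x_a`, i.e. the
#' regulatory input of the mRNA rate equation.
#'
#' @inheritParams xapr_active_fraction
#' @param pol_term Polymerase saturation factor (1 in nondimensional mode).
#' @return Activity in `[0, pol_term)`, vectorized over `x_a`.
#' @export
promoter_activity <- function(x_a, params, variant = NULL, pol_term = 1) {
  variant <- .check_variant(variant)
  r <- params$XapR_R * xapr_active_fraction(x_a, params, variant)
  promoter_active_probability(r, params, variant, pol_term)
}

#' Mean mRNA concentration implied by the inducer level
#'
#' The stationary mean of the mRNA rate equation at fixed regulatory
#' input: `(rho_m / gamma_mp) * p_active(x_a)`, in units of K_a.  At a
#' fixed point of the full system this equals the mRNA component of the
#' fixed point.
#'
#' @inheritParams xapr_active_fraction
#' @return Mean nondimensional mRNA concentration, vectorized over `x_a`.
#' @export
mean_mrna <- function(x_a, params, variant = NULL) {
  params$rho_m / params$gamma_mp * promoter_activity(x_a, params, variant)
}

## d p_active / d x_a, analytic (used by the Jacobian)
promoter_activity_deriv <- function(x_a, params, variant = NULL) {
  variant <- .check_variant(variant)
  n <- variant$inducer_sites
  KxA <- params$K_chiA
  u <- x_a / KxA
  a <- (1 + u)^n
  b <- exp(params$deps_x) * (1 + u / params$K_IA)^n
  da <- n * (1 + u)^(n - 1) / KxA
  db <- exp(params$deps_x) * n * (1 + u / params$K_IA)^(n - 1) /
    (KxA * params$K_IA)
  f <- a / (a + b)
  df <- (da * b - a * db) / (a + b)^2
  r <- params$XapR_R * f
  dr <- params$XapR_R * df
  if (variant$promoter_sites == 1L) {
    dh <- 1 / (1 + r)^2
  } else {
    E <- exp(effective_deps_coop(params, variant))
    z <- 1 + 2 * r + r^2 * E
    dh <- switch(variant$active_policy,
      fully_occupied_only = 2 * r * E * (1 + r) / z^2,
      any_xapr_bound      = 2 * (1 + r * E) / z^2)
  }
  dh * dr
}
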