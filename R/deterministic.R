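## Fixed points, stability, the mRNA quasi-steady-state reduction,
## trajectory integration, bifurcation diagrams and bistable-range scans.

## scalar steady-state function g(x_a): eliminate m_a and p_a through
## m_a* = (rho_m/gamma_mp) p_active(x_a), p_a* = rho_p m_a* = rho p_active,
## leaving one equation in x_a
steady_state_residual <- function(x_a, params, variant = NULL) {
  variant <- .check_variant(variant)
  act <- promoter_activity(x_a, params, variant)
  p <- params$rho * act
  transport_flux(x_a, params, variant) * p +
    params$k_eta * (params$c_a - params$xi * x_a)
}

.STABILITY_EPS <- 1e-9  # dead zone around zero real part (fold vicinity)

classify_stability <- function(eig) {
  re <- Re(eig)
  if (any(abs(re) < .STABILITY_EPS)) "marginal"
  else if (all(re < 0)) "stable"
  else "unstable"
}

#' Find the fixed points of the switch
#'
#' Locates all nonnegative steady states of the nondimensional system.
#' The mRNA and protein equations are eliminated analytically
#' (`m_a = (rho_m/gamma_mp) p_active(x_a)`, `p_a = rho p_active(x_a)`),
#' leaving a single scalar equation in `x_a` that is bracketed by sign
#' changes on a logarithmic grid and refined by bisection.  Each root is
#' back-substituted and verified against the full three-dimensional
#' right-hand side; stability is classified from the eigenvalues of the
#' analytic Jacobian.
#'
#' @param params An [xap_params()] object.
#' @param variant Optional [circuit_variant()].
#' @param x_range Search interval for `x_a` (log-spaced), default
#'   `c(1e-6, 1e8)`.
#' @param n_grid Number of grid points, default 2000.
#' @param tol Relative root tolerance, default 1e-10.
#' @return An object of class `xap_fixed_points`: a data frame with one
#'   row per fixed point (ordered by `p_a`), columns `index`, `m_a`,
#'   `p_a`, `x_a`, `stability`, `eig_re_max`, and an `"eigenvalues"`
#'   attribute (list of complex eigenvalue triples).
#' @export
#' @examples
#' fp <- find_fixed_points(xap_params())
#' fp            # three fixed points: stable / unstable / stable
find_fixed_points <- function(params, variant = NULL,
                              x_range = c(1e-6, 1e8), n_grid = 2000,
                              tol = 1e-10) {
  variant <- .check_variant(variant)
  stopifnot(length(x_range) == 2L, all(x_range > 0), diff(x_range) > 0)
  g <- function(x) steady_state_residual(x, params, variant)
  grid <- exp(seq(log(x_range[1]), log(x_range[2]), length.out = n_grid))
  ## x_a = 0 is a steady state only when c_a -> 0; include the origin so
  ## that degenerate configurations are not missed by the log grid
  grid <- c(0, grid)
  gv <- g(grid)  # steady_state_residual is vectorized in x_a
  roots <- grid[gv == 0]
  sc <- which(gv[-1] * gv[-length(gv)] < 0)
  for (i in sc) {
    r <- uniroot(g, c(grid[i], grid[i + 1]),
                 tol = tol * max(grid[i + 1], 1))$root
    roots <- c(roots, r)
  }
  if (length(roots) > 0 &&
      (abs(gv[2]) > 0 && min(roots) <= grid[2] ||
       max(roots) >= grid[length(grid) - 1]))
    warning("a root lies at the edge of 'x_range'; widen the scan ",
            "bounds to exclude missed roots")
  roots <- sort(roots)
  ## drop near-duplicates (relative 1e-6)
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-6 * pmax(roots[-1], 1e-12))
    roots <- roots[keep]
  }
  act <- promoter_activity(roots, params, variant)
  m <- params$rho_m / params$gamma_mp * act
  p <- params$rho * act
  ## verify each root against the full 3D right-hand side, component-wise
  ## relative to the magnitudes of its constituent terms
  ok <- vapply(seq_along(roots), function(i) {
    st <- c(m[i], p[i], roots[i])
    r3 <- xap_rhs(st, params, variant)
    scale <- c(params$rho_m * act[i] + params$gamma_mp * m[i],
               params$rho_p * m[i] + p[i],
               abs(transport_flux(roots[i], params, variant) * p[i]) +
                 params$k_eta * (params$c_a + params$xi * roots[i]))
    all(abs(r3) <= 1e-9 * pmax(scale, 1e-300))
  }, logical(1))
  if (!all(ok))
    warning("dropped ", sum(!ok), " root(s) failing steady-state ",
            "verification against the full system")
  roots <- roots[ok]; m <- m[ok]; p <- p[ok]
  ord <- order(p, roots)
  roots <- roots[ord]; m <- m[ord]; p <- p[ord]
  eigs <- lapply(seq_along(roots), function(i) {
    J <- xap_jacobian(c(m[i], p[i], roots[i]), params, variant)
    eigen(J, only.values = TRUE)$values
  })
  out <- data.frame(
    index = seq_along(roots),
    m_a = m, p_a = p, x_a = roots,
    stability = vapply(eigs, classify_stability, character(1)),
    eig_re_max = vapply(eigs, function(e) max(Re(e)), numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "eigenvalues") <- eigs
  class(out) <- c("xap_fixed_points", "data.frame")
  out
}

#' @export
print.xap_fixed_points <- function(x, ...) {
  cat(nrow(x), "fixed point(s)\n")
  print.data.frame(x, digits = 6)
  invisible(x)
}

#' mRNA quasi-steady-state reduction to two dimensions
#'
#' Eliminates the (fast) mRNA variable by solving its rate equation at
#' steady state, `m_a(x_a) = (rho_m / gamma_mp) p_active(x_a)`, which
#' reduces the system to the `(p_a, x_a)` plane:
#' \deqn{\dot p_a = \rho\, p_{active}(x_a) - p_a, \qquad
#'   \rho = \rho_m \rho_p / \gamma_{mp}}
#' with the inducer equation unchanged.  The fixed points of the reduced
#' system coincide with the `(p_a, x_a)` projections of the
#' three-dimensional fixed points.
#'
#' @inheritParams find_fixed_points
#' @return A list of class `xap_reduced_system` with elements
#'   `rhs(state)` (the reduced right-hand side, `state = c(p_a, x_a)`),
#'   `jacobian(state)` (its 2x2 analytic Jacobian),
#'   `mrna_qss(x_a)` (the eliminated mRNA level),
#'   `protein_nullcline(x_a)` (`p_a = rho * p_active(x_a)`), and
#'   `xanthosine_nullcline(x_a)` (the `p_a` on which the inducer
#'   equation vanishes; `NA` where the per-protein flux is zero).
#' @export
reduce_mrna_qss <- function(params, variant = NULL) {
  variant <- .check_variant(variant)
  force(params)
  rhs2 <- function(state) {
    p <- state[[1]]; x <- state[[2]]
    c(params$rho * promoter_activity(x, params, variant) - p,
      transport_flux(x, params, variant) * p +
        params$k_eta * (params$c_a - params$xi * x))
  }
  jac2 <- function(state) {
    p <- state[[1]]; x <- state[[2]]
    rbind(
      c(-1, params$rho * promoter_activity_deriv(x, params, variant)),
      c(transport_flux(x, params, variant),
        transport_flux_deriv(x, params, variant) * p -
          params$k_eta * params$xi)
    )
  }
  structure(list(
    rhs = rhs2,
    jacobian = jac2,
    mrna_qss = function(x_a)
      params$rho_m / params$gamma_mp * promoter_activity(x_a, params, variant),
    protein_nullcline = function(x_a)
      params$rho * promoter_activity(x_a, params, variant),
    xanthosine_nullcline = function(x_a) {
      flux <- transport_flux(x_a, params, variant)
      ifelse(flux == 0, NA_real_,
             -params$k_eta * (params$c_a - params$xi * x_a) / flux)
    },
    params = params, variant = variant
  ), class = "xap_reduced_system")
}

#' Integrate a trajectory of the deterministic system
#'
#' Stiff-capable integration of [xap_rhs()] with the analytic Jacobian
#' supplied to the solver.  The state stays nonnegative up to solver
#' tolerance; tiny negative excursions are clamped to zero in the
#' returned table.
#'
#' @param params An [xap_params()] object.
#' @param initial Initial state `c(m_a, p_a, x_a)`, nonnegative.
#' @param tau_end Integration horizon in units of 1/gamma_p.
#' @param variant Optional [circuit_variant()].
#' @param n_out Number of equally spaced output times (default 500).
#' @param gamma_p Protein decay rate (1/s) used only to report the
#'   dimensional time column, default 5e-4.
#' @param atol,rtol Solver tolerances (the mRNA component is of order
#'   1e-4 in the reference scenario, hence the tight absolute tolerance).
#' @return A data frame of class `xap_trajectory` with columns `tau`,
#'   `t_seconds`, `m_a`, `p_a`, `x_a`.
#' @export
integrate_trajectory <- function(params, initial = c(0, 0, 0), tau_end,
                                 variant = NULL, n_out = 500,
                                 gamma_p = 5e-4,
                                 atol = 1e-12, rtol = 1e-8) {
  variant <- .check_variant(variant)
  if (any(initial < 0) || any(!is.finite(initial)))
    stop("'initial' must be finite and nonnegative")
  stopifnot(tau_end > 0)
  times <- seq(0, tau_end, length.out = n_out)
  sol <- deSolve::ode(
    y = setNames(as.numeric(initial), c("m_a", "p_a", "x_a")),
    times = times,
    func = function(t, y, parms) {
      yc <- pmax(y, 0)
      list(xap_rhs(yc, params, variant))
    },
    jacfunc = function(t, y, parms) xap_jacobian(pmax(y, 0), params, variant),
    jactype = "fullusr",
    parms = NULL, method = "lsoda", atol = atol, rtol = rtol
  )
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(sol, "istate")[1],
         ") at tau ~ ", max(sol[, 1]))
  out <- as.data.frame(sol)
  names(out)[1] <- "tau"
  out$t_seconds <- out$tau / gamma_p
  out[c("m_a", "p_a", "x_a")] <- lapply(out[c("m_a", "p_a", "x_a")],
                                        function(v) pmax(v, 0))
  out <- out[c("tau", "t_seconds", "m_a", "p_a", "x_a")]
  class(out) <- c("xap_trajectory", "data.frame")
  out
}

#' Bifurcation diagram over a control parameter
#'
#' Runs [find_fixed_points()] for every value of a control parameter
#' (default the extracellular inducer concentration `c_a`), links the
#' branches between neighbouring grid values by nearest distance in
#' `log(p_a)` (ties broken toward preserving the stability class), and
#' refines the fold (saddle-node) locations by bisection on the change
#' of branch count.
#'
#' @param params An [xap_params()] object.
#' @param control Name of the scanned parameter, default `"c_a"`.
#' @param values Sorted positive grid of control values.
#' @param variant Optional [circuit_variant()].
#' @param refine_folds Refine fold locations by bisection (default TRUE).
#' @param fold_tol Relative tolerance of the fold bisection, default 1e-4.
#' @param ... Passed on to [find_fixed_points()].
#' @return An object of class `xap_bifurcation`: a data frame with
#'   columns `control_value`, `branch_index`, `m_a`, `p_a`, `x_a`,
#'   `stability`, `eig_re_max`; attributes `"control"` and `"folds"`
#'   (refined control values where the branch count changes).
#' @export
bifurcation_diagram <- function(params, control = "c_a", values,
                                variant = NULL, refine_folds = TRUE,
                                fold_tol = 1e-4, ...) {
  variant <- .check_variant(variant)
  if (!control %in% .NONDIM_FIELDS)
    stop("unknown control parameter: ", control)
  if (is.unsorted(values) || any(values <= 0))
    stop("'values' must be a sorted positive grid")
  fp_at <- function(v) {
    args <- list(params); args[[control]] <- v
    find_fixed_points(do.call(update_params, args), variant = variant, ...)
  }
  fps <- lapply(values, fp_at)
  counts <- vapply(fps, nrow, integer(1))
  ## nearest-log-distance branch linking
  nb <- max(counts)
  prev_lab <- NULL; next_lab <- 1L
  rows <- vector("list", length(values))
  prev_tab <- NULL
  for (i in seq_along(values)) {
    tab <- fps[[i]]
    lab <- integer(nrow(tab))
    if (is.null(prev_tab) || nrow(prev_tab) == 0L || nrow(tab) == 0L) {
      lab <- seq_len(nrow(tab)) + next_lab - 1L
      next_lab <- next_lab + nrow(tab)
    } else {
      used <- logical(nrow(prev_tab))
      ord <- order(tab$p_a)
      for (j in ord) {
        d <- abs(log(pmax(tab$p_a[j], 1e-300)) -
                 log(pmax(prev_tab$p_a, 1e-300)))
        d[used] <- Inf
        ## prefer continuation within the same stability class
        same <- prev_tab$stability == tab$stability[j]
        d[!same] <- d[!same] + 1e-9
        k <- which.min(d)
        if (is.finite(d[k])) {
          lab[j] <- prev_lab[k]; used[k] <- TRUE
        } else {
          lab[j] <- next_lab; next_lab <- next_lab + 1L
        }
      }
    }
    rows[[i]] <- cbind(control_value = values[i], tab, branch_index = lab)
    prev_tab <- tab; prev_lab <- lab
  }
  out <- do.call(rbind, rows)
  out <- out[c("control_value", "branch_index", "m_a", "p_a", "x_a",
               "stability", "eig_re_max")]
  folds <- numeric(0)
  if (refine_folds && length(values) > 1) {
    n_at <- function(v) nrow(fp_at(v))
    for (i in which(diff(counts) != 0)) {
      lo <- values[i]; hi <- values[i + 1]
      nlo <- counts[i]
      while ((hi - lo) > fold_tol * hi) {
        mid <- sqrt(lo * hi)
        if (n_at(mid) == nlo) lo <- mid else hi <- mid
      }
      folds <- c(folds, sqrt(lo * hi))
    }
  } else if (length(values) > 1 && any(diff(counts) != 0)) {
    warning("branch count changes between grid points; folds not refined")
  }
  structure(out, control = control, folds = folds, counts = counts,
            class = c("xap_bifurcation", "data.frame"))
}

#' @export
print.xap_bifurcation <- function(x, ...) {
  cat("Bifurcation diagram over", attr(x, "control"), "-",
      length(unique(x$control_value)), "grid values,",
      max(x$branch_index), "branch(es)\n")
  folds <- attr(x, "folds")
  if (length(folds) > 0)
    cat("fold points at", attr(x, "control"), "=",
        paste(signif(folds, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Critical parameter values bounding bistability
#'
#' Scans one parameter (all others held fixed) for the boundary of the
#' bistable region, defined as three coexisting fixed points, and
#' refines each boundary by bisection.
#'
#' @param params An [xap_params()] object.
#' @param parameter Name of the scanned parameter.
#' @param bounds Positive scan interval `c(lo, hi)`.
#' @param variant Optional [circuit_variant()].
#' @param n_scan Coarse log-grid size used to locate transitions,
#'   default 25.
#' @param tol Relative bisection tolerance, default 1e-3.
#' @param ... Passed on to [find_fixed_points()].
#' @return A list with `critical` (numeric vector of refined boundary
#'   values, possibly empty), `bistable_anywhere`, and the coarse scan
#'   table `scan` (`value`, `n_fixed_points`).  If the system is
#'   monostable (or bistable) throughout the bounds, `critical` is empty
#'   and a message records the fact.
#' @export
bistable_range <- function(params, parameter, bounds, variant = NULL,
                           n_scan = 25, tol = 1e-3, ...) {
  variant <- .check_variant(variant)
  if (!parameter %in% .NONDIM_FIELDS)
    stop("unknown parameter: ", parameter)
  stopifnot(length(bounds) == 2L, all(bounds > 0), diff(bounds) > 0)
  n_at <- function(v) {
    args <- list(params); args[[parameter]] <- v
    nrow(find_fixed_points(do.call(update_params, args),
                           variant = variant, ...))
  }
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_scan))
  ns <- vapply(grid, n_at, integer(1))
  bist <- ns == 3L
  critical <- numeric(0)
  if (!any(bist)) {
    message("no bistable region found for '", parameter,
            "' within the scan bounds")
  } else if (all(bist)) {
    message("bistable throughout the scan bounds for '", parameter, "'")
  } else {
    for (i in which(diff(bist) != 0)) {
      lo <- grid[i]; hi <- grid[i + 1]; blo <- bist[i]
      while ((hi - lo) > tol * hi) {
        mid <- sqrt(lo * hi)
        if ((n_at(mid) == 3L) == blo) lo <- mid else hi <- mid
      }
      critical <- c(critical, sqrt(lo * hi))
    }
  }
  list(critical = critical, bistable_anywhere = any(bist),
       scan = data.frame(value = grid, n_fixed_points = ns))
}
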