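## Discrete-molecule realization of the model: reaction networks,
## Gillespie direct and hybrid tau-leap simulation, ensembles, bimodality
## splitting, adaptation times and the hysteresis protocol.

#' Cell geometry: molecules per nondimensional concentration unit
#'
#' Conversion between nondimensional concentrations (units of K_a) and
#' molecule counts: `Omega = N_Avogadro * volume * K_a`.  With the
#' defaults (a typical E. coli cytoplasmic volume of 1 fL and
#' `K_a = 5e-5` M) `Omega ~ 3.01e4`, which puts the reference scenario
#' at around 5 proteins in the low state, a few hundred in the high
#' state, of order one mRNA at the switch point, and xanthosine counts
#' up to ~1e7.
#'
#' @param volume Cytoplasmic volume in litres, default 1e-15 (1 fL).
#' @param K_a Concentration scale in molar, default 5e-5.
#' @return An object of class `cell_geometry` with fields `volume`,
#'   `K_a` and `Omega`.
#' @export
cell_geometry <- function(volume = 1e-15, K_a = 5e-5) {
  stopifnot(is.numeric(volume), volume > 0, is.numeric(K_a), K_a > 0)
  structure(list(volume = volume, K_a = K_a,
                 Omega = .N_AVOGADRO * volume * K_a),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Cell geometry: V = %g L, K_a = %g M, Omega = %g molecules\n",
              x$volume, x$K_a, x$Omega))
  invisible(x)
}

#' Counts/concentration conversion
#'
#' @param x Counts or nondimensional concentrations.
#' @param geom A [cell_geometry()] object.
#' @return The converted quantity.
#' @export
counts_to_conc <- function(x, geom) x / geom$Omega

#' @rdname counts_to_conc
#' @param rounding Rounding policy for `conc_to_counts`: `"half_up"`
#'   (default) or `"none"` (keep fractional counts).
#' @export
conc_to_counts <- function(x, geom, rounding = c("half_up", "none")) {
  rounding <- match.arg(rounding)
  v <- x * geom$Omega
  if (rounding == "half_up") floor(v + 0.5) else v
}

## ---------------------------------------------------------------------------
## Reaction networks

#' Generic typed reaction network
#'
#' Low-level constructor for the jump-process networks the simulators
#' run.  Most users want [build_network()], which assembles the switch
#' model; this constructor also serves small test systems (e.g. a
#' birth-death process).
#'
#' Each reaction is a list with fields:
#' \describe{
#'   \item{type}{`"constant"`, `"linear"`, `"mm"` or `"regulated"`.}
#'   \item{rate}{Rate constant (propensity per unit tau).}
#'   \item{scale_sp}{Species whose count multiplies the propensity
#'     (for `"linear"` and optionally `"mm"`), name or NA.}
#'   \item{mm_sp}{Species whose concentration enters the
#'     Michaelis-Menten or regulatory factor, name or NA.}
#'   \item{mm_K}{Michaelis constant (nondimensional), for `"mm"`.}
#'   \item{burst_mean}{Mean geometric burst size (1 = no burst).}
#' }
#'
#' @param species Character vector of species names.
#' @param stoich Integer matrix (species x reactions) of count changes.
#' @param reactions List of reaction descriptors (see Details).
#' @param omega Molecules per nondimensional concentration unit.
#' @param regulation Numeric vector of regulatory parameters for
#'   `"regulated"` reactions (assembled by [build_network()]); a default
#'   placeholder is used when no regulated reaction exists.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, stoich, reactions, omega = 1,
                             regulation = NULL) {
  stoich <- as.matrix(stoich)
  storage.mode(stoich) <- "integer"
  stopifnot(nrow(stoich) == length(species),
            ncol(stoich) == length(reactions))
  rownames(stoich) <- species
  sp_idx <- function(nm) {
    if (is.null(nm) || is.na(nm)) return(-1L)
    i <- match(nm, species)
    if (is.na(i)) stop("unknown species: ", nm)
    i - 1L
  }
  types <- c(constant = 0L, linear = 1L, mm = 2L, regulated = 3L)
  type <- integer(length(reactions))
  rate <- mm_K <- burst_mean <- numeric(length(reactions))
  scale_sp <- mm_sp <- burst_sp <- integer(length(reactions))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    if (!r$type %in% names(types)) stop("unknown reaction type: ", r$type)
    type[j] <- types[[r$type]]
    rate[j] <- r$rate
    if (rate[j] < 0 || !is.finite(rate[j]))
      stop("reaction rates must be finite and nonnegative")
    scale_sp[j] <- sp_idx(r$scale_sp %||% NA)
    mm_sp[j] <- sp_idx(r$mm_sp %||% NA)
    mm_K[j] <- r$mm_K %||% 0
    burst_mean[j] <- r$burst_mean %||% 1
    if (burst_mean[j] < 1) stop("'burst_mean' must be >= 1")
    if (type[j] == 1L && scale_sp[j] < 0)
      stop("'linear' reactions need a scale_sp")
    if (type[j] %in% c(2L, 3L) && mm_sp[j] < 0)
      stop("'mm'/'regulated' reactions need an mm_sp")
    ## bursts inflate the single +1 product of the reaction
    if (burst_mean[j] > 1) {
      prod <- which(stoich[, j] > 0)
      if (length(prod) != 1L || stoich[prod, j] != 1L)
        stop("bursty reactions must have exactly one +1 product")
      burst_sp[j] <- prod - 1L
    } else burst_sp[j] <- -1L
  }
  if (is.null(regulation)) {
    if (any(type == 3L))
      stop("'regulated' reactions require a regulation parameter vector")
    regulation <- c(1, 1, 0, 0, 0, 2, 2, 0)
  }
  structure(list(species = species, stoich = stoich, reactions = reactions,
                 omega = omega, regulation = regulation,
                 .type = type, .rate = rate, .scale_sp = scale_sp,
                 .mm_sp = mm_sp, .mm_K = mm_K, .burst_mean = burst_mean,
                 .burst_sp = burst_sp),
            class = "reaction_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", length(x$species), "species (",
      paste(x$species, collapse = ", "), "),",
      ncol(x$stoich), "reactions, Omega =", format(x$omega), "\n")
  invisible(x)
}

#' Build the discrete-molecule network of the switch
#'
#' Assembles the jump-process realization of the rate equations for
#' species `M` (mRNA), `P` (protein) and `X` (intracellular inducer),
#' with propensities chosen so that the macroscopic equations are
#' recovered in the large-`Omega` limit (density-preserving scaling).
#' Transcription evaluates the MWC/promoter regulatory functions at the
#' concentration-converted inducer count.
#'
#' Reactions: transcription (`0 -> M`, rate `rho_m * Omega *
#' p_active(X/Omega)`), mRNA decay (`gamma_mp * M`), translation
#' (`M -> M + P`, rate `rho_p * M`), protein decay (`P`), XapB import
#' (`0 -> X`, rate `k_beta_i c_a/(K_beta_i + c_a) * P`), XapB export and
#' XapA degradation (`X -> 0`, Michaelis-Menten in `X/Omega` scaled by
#' `P`), non-specific influx (`k_eta c_a Omega`) and efflux
#' (`k_eta xi X`).  Variant flags drop the XapA/XapB channels.
#'
#' @param params An [xap_params()] object.
#' @param geom A [cell_geometry()] object.
#' @param variant Optional [circuit_variant()].
#' @param bursts Add geometric bursts to transcription and translation
#'   (default FALSE).
#' @param burst_mean_mrna,burst_mean_protein Mean burst sizes (>= 1)
#'   used when `bursts = TRUE`; the defaults of 1 are conservative (no
#'   burst) since burst statistics are system-specific.
#' @return A `reaction_network` over species `M`, `P`, `X`.
#' @export
build_network <- function(params, geom = cell_geometry(), variant = NULL,
                          bursts = FALSE, burst_mean_mrna = 1,
                          burst_mean_protein = 1) {
  variant <- .check_variant(variant)
  stopifnot(inherits(geom, "cell_geometry"))
  if (bursts && (burst_mean_mrna < 1 || burst_mean_protein < 1))
    stop("burst means must be >= 1 when bursts are enabled")
  bm <- if (bursts) burst_mean_mrna else 1
  bp <- if (bursts) burst_mean_protein else 1
  Omega <- geom$Omega
  species <- c("M", "P", "X")
  rx <- list(); st <- list()
  add <- function(r, s) { rx[[length(rx) + 1]] <<- r; st[[length(st) + 1]] <<- s }
  add(list(name = "transcription", type = "regulated",
           rate = params$rho_m * Omega, mm_sp = "X", burst_mean = bm),
      c(1, 0, 0))
  add(list(name = "mrna_decay", type = "linear",
           rate = params$gamma_mp, scale_sp = "M"), c(-1, 0, 0))
  add(list(name = "translation", type = "linear",
           rate = params$rho_p, scale_sp = "M", burst_mean = bp), c(0, 1, 0))
  add(list(name = "protein_decay", type = "linear", rate = 1,
           scale_sp = "P"), c(0, -1, 0))
  if (!variant$xapB_removed) {
    add(list(name = "xapB_import", type = "linear",
             rate = params$k_beta_i * params$c_a /
               (params$K_beta_i + params$c_a),
             scale_sp = "P"), c(0, 0, 1))
    add(list(name = "xapB_export", type = "mm", rate = params$k_beta_e,
             mm_sp = "X", mm_K = params$K_beta_e, scale_sp = "P"),
        c(0, 0, -1))
  }
  if (!variant$xapA_removed) {
    add(list(name = "xapA_degradation", type = "mm", rate = params$k_alpha,
             mm_sp = "X", mm_K = 1, scale_sp = "P"), c(0, 0, -1))
  }
  add(list(name = "nup_influx", type = "constant",
           rate = params$k_eta * params$c_a * Omega), c(0, 0, 1))
  add(list(name = "nup_efflux", type = "linear",
           rate = params$k_eta * params$xi, scale_sp = "X"), c(0, 0, -1))
  regulation <- c(params$K_chiA, params$K_IA, params$deps_x, params$XapR_R,
                  effective_deps_coop(params, variant),
                  variant$inducer_sites, variant$promoter_sites,
                  if (variant$active_policy == "any_xapr_bound") 1 else 0)
  net <- reaction_network(species, do.call(cbind, st), rx, omega = Omega,
                          regulation = regulation)
  attr(net, "params") <- params
  attr(net, "variant") <- variant
  attr(net, "geom") <- geom
  net
}

#' Propensities of a network at given counts
#'
#' Evaluates every reaction propensity at integer counts `n`; useful for
#' mean-field consistency checks (`stoich %*% propensities` equals
#' `Omega` times the macroscopic right-hand side at the matching
#' concentrations).
#'
#' @param network A `reaction_network`.
#' @param counts Nonnegative numeric vector of counts, one per species.
#' @return Named numeric vector of propensities.
#' @export
network_propensities <- function(network, counts) {
  stopifnot(inherits(network, "reaction_network"),
            length(counts) == length(network$species))
  if (any(counts < 0)) stop("counts must be nonnegative")
  reg <- network$regulation
  p_act <- function(x) {
    u <- x / reg[1]
    ns <- reg[6]
    act <- (1 + u)^ns
    inact <- exp(reg[3]) * (1 + u / reg[2])^ns
    r <- reg[4] * act / (act + inact)
    if (reg[7] == 1) return(r / (1 + r))
    E <- exp(reg[5]); z <- 1 + 2 * r + r^2 * E
    if (reg[8] == 1) (2 * r + r^2 * E) / z else r^2 * E / z
  }
  a <- numeric(ncol(network$stoich))
  for (j in seq_along(a)) {
    ty <- network$.type[j]; rt <- network$.rate[j]
    a[j] <- switch(as.character(ty),
      "0" = rt,
      "1" = rt * counts[network$.scale_sp[j] + 1L],
      "2" = {
        x <- counts[network$.mm_sp[j] + 1L] / network$omega
        rt * x / (network$.mm_K[j] + x) *
          (if (network$.scale_sp[j] >= 0) counts[network$.scale_sp[j] + 1L] else 1)
      },
      "3" = rt * p_act(counts[network$.mm_sp[j] + 1L] / network$omega))
  }
  names(a) <- vapply(network$reactions,
                     function(r) r$name %||% r$type, character(1))
  a
}

## ---------------------------------------------------------------------------
## Simulation

.sim_call <- function(fun, network, initial, t_end, record_times,
                      monitor_species, monitor_value, ...) {
  stopifnot(inherits(network, "reaction_network"))
  initial <- as.numeric(initial)
  if (length(initial) != length(network$species))
    stop("'initial' must have one count per species")
  if (any(initial < 0) || any(initial != floor(initial)))
    stop("'initial' must be nonnegative integer counts")
  if (t_end <= 0) stop("'t_end' must be positive")
  mon_sp <- -1L; mon_val <- Inf
  if (!is.null(monitor_species)) {
    mon_sp <- match(monitor_species, network$species) - 1L
    if (is.na(mon_sp)) stop("unknown monitor species: ", monitor_species)
    mon_val <- monitor_value
  }
  if (is.null(record_times)) record_times <- numeric(0)
  fun(network$stoich, network$.type, network$.rate, network$.scale_sp,
      network$.mm_sp, network$.mm_K, network$.burst_mean, network$.burst_sp,
      network$regulation, network$omega, initial, t_end,
      as.numeric(record_times), ..., mon_sp, mon_val)
}

.sim_result <- function(res, network, record_times, seed, algorithm) {
  traj <- NULL
  if (length(record_times) > 0) {
    traj <- as.data.frame(res$states)
    names(traj) <- network$species
    traj <- cbind(tau = as.numeric(record_times), traj)
  }
  structure(list(
    final = setNames(res$final, network$species),
    t_final = res$t_final, n_events = res$n_events,
    status = res$status,
    truncated = res$status == 1,
    trajectory = traj,
    first_passage = res$first_passage,
    seed = seed, algorithm = algorithm
  ), class = "xap_sim")
}

#' @export
print.xap_sim <- function(x, ...) {
  cat(sprintf("%s simulation to tau = %g (%g events/steps, status %d)\n",
              x$algorithm, x$t_final, x$n_events, x$status))
  cat("final counts:", paste(names(x$final), x$final, sep = "=",
                             collapse = "  "), "\n")
  invisible(x)
}

#' Exact stochastic simulation (Gillespie's direct method)
#'
#' Statistically exact sample path of the jump process.  With the same
#' seed, network and arguments the event sequence is bit-identical.
#'
#' @param network A `reaction_network`.
#' @param initial Nonnegative integer initial counts (one per species).
#' @param t_end Simulation horizon in units of 1/gamma_p.
#' @param seed Integer RNG seed.
#' @param record_times Optional increasing vector of sampling times; the
#'   state is recorded left-continuously at each.
#' @param max_events Event-count bound; if hit, the run is flagged
#'   truncated (`status = 1`) rather than silently stopped.
#' @param monitor_species,monitor_value Optional first-passage monitor:
#'   the first time the species' count reaches `monitor_value` is
#'   reported in `first_passage` (NA if never).
#' @return An object of class `xap_sim` with fields `final`, `t_final`,
#'   `n_events`, `status` (0 ok, 1 truncated, 2 propensity overflow),
#'   `trajectory` (if recorded), `first_passage`.
#' @export
simulate_direct <- function(network, initial, t_end, seed = 1,
                            record_times = NULL, max_events = 1e8,
                            monitor_species = NULL, monitor_value = Inf) {
  set.seed(seed)
  res <- .sim_call(ssa_direct_cpp, network, initial, t_end, record_times,
                   monitor_species, monitor_value, max_events)
  if (res$status == 2)
    stop("propensity overflow (non-finite or negative propensity)")
  .sim_result(res, network, record_times, seed, "direct")
}

#' Hybrid exact / tau-leap stochastic simulation
#'
#' Advances abundant, fast reaction channels by tau-leaping (Poisson
#' firing numbers with a bounded-relative-change leap size) and rare or
#' low-count channels by the exact direct method.  The partition is
#' re-evaluated at every macro-step: a channel is leapable when every
#' species it changes exceeds `count_thresh` and its propensity exceeds
#' `rate_thresh`.  Candidate leaps that would drive a count negative are
#' retried with halved step size.
#'
#' @inheritParams simulate_direct
#' @param eps Bounded relative-change parameter of the leap-size
#'   criterion, default 0.03.
#' @param count_thresh Minimum count of every species changed by a
#'   leapable channel, default 100.
#' @param rate_thresh Minimum propensity (per unit tau) of a leapable
#'   channel, default 1e3.
#' @param max_steps Macro-step bound (truncation guard).
#' @return An `xap_sim` object; `status = 3` flags a tau underflow
#'   (system too stiff for the thresholds).
#' @export
simulate_hybrid <- function(network, initial, t_end, seed = 1,
                            record_times = NULL, eps = 0.03,
                            count_thresh = 100, rate_thresh = 1e3,
                            max_steps = 1e8,
                            monitor_species = NULL, monitor_value = Inf) {
  set.seed(seed)
  res <- .sim_call(ssa_hybrid_cpp, network, initial, t_end, record_times,
                   monitor_species, monitor_value,
                   max_steps, eps, count_thresh, rate_thresh)
  if (res$status == 2)
    stop("propensity overflow (non-finite or negative propensity)")
  if (res$status == 3)
    stop("tau underflow: leap size collapsed below 2^-60 of the ",
         "candidate step; the partition thresholds are too aggressive ",
         "for this system")
  .sim_result(res, network, record_times, seed, "hybrid")
}

#' Ensemble of independent stochastic runs
#'
#' Runs `n_runs` independent seeded simulations and collects endpoint
#' counts (and optionally trajectories and first-passage times).  Run
#' seeds are `base_seed + 0:(n_runs-1)`.  Runs that hit the event bound
#' are kept and flagged, not dropped.
#'
#' @param network A `reaction_network`.
#' @param initial Initial counts, one per species.
#' @param t_end Horizon in units of 1/gamma_p.
#' @param n_runs Number of runs (>= 1).
#' @param base_seed First RNG seed.
#' @param algorithm `"hybrid"` (default) or `"direct"`.
#' @param record_times Optional sampling grid; when supplied,
#'   per-run trajectories are stored.
#' @param monitor_species,monitor_value Optional first-passage monitor
#'   (see [simulate_direct()]).
#' @param ... Further arguments for the chosen simulator.
#' @return An object of class `xap_ensemble`: list with `endpoints`
#'   (n_runs x species matrix), `first_passage`, `statuses`, `seeds`,
#'   `t_end`, `algorithm`, `trajectories` (list or NULL), and the
#'   network.
#' @export
run_ensemble <- function(network, initial, t_end, n_runs, base_seed = 1,
                         algorithm = c("hybrid", "direct"),
                         record_times = NULL,
                         monitor_species = NULL, monitor_value = Inf, ...) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_runs >= 1)
  simfun <- if (algorithm == "hybrid") simulate_hybrid else simulate_direct
  seeds <- base_seed + seq_len(n_runs) - 1L
  endpoints <- matrix(NA_real_, n_runs, length(network$species),
                      dimnames = list(NULL, network$species))
  fp <- rep(NA_real_, n_runs)
  statuses <- integer(n_runs)
  trajs <- if (!is.null(record_times)) vector("list", n_runs) else NULL
  for (i in seq_len(n_runs)) {
    s <- simfun(network, initial, t_end, seed = seeds[i],
                record_times = record_times,
                monitor_species = monitor_species,
                monitor_value = monitor_value, ...)
    endpoints[i, ] <- s$final
    fp[i] <- s$first_passage
    statuses[i] <- s$status
    if (!is.null(trajs)) trajs[[i]] <- s$trajectory
  }
  if (any(statuses != 0))
    warning(sum(statuses != 0), " run(s) were truncated at the ",
            "event/step bound; they are retained and flagged")
  structure(list(endpoints = endpoints, first_passage = fp,
                 statuses = statuses, seeds = seeds, t_end = t_end,
                 algorithm = algorithm, initial = initial,
                 trajectories = trajs,
                 monitor_species = monitor_species,
                 monitor_value = monitor_value,
                 network = network),
            class = "xap_ensemble")
}

#' @export
print.xap_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d %s runs to tau = %g\n",
              nrow(x$endpoints), x$algorithm, x$t_end))
  cat("endpoint means:",
      paste(colnames(x$endpoints), signif(colMeans(x$endpoints), 5),
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Endpoint histogram of an ensemble
#'
#' @param ensemble An `xap_ensemble`.
#' @param species Species name.
#' @param breaks Passed to [graphics::hist()] semantics via [hist()]'s
#'   default binning (computed with `hist(plot = FALSE)`).
#' @return The `histogram` object.
#' @export
ensemble_histogram <- function(ensemble, species = "P", breaks = "Sturges") {
  stopifnot(inherits(ensemble, "xap_ensemble"))
  v <- ensemble$endpoints[, species]
  graphics::hist(v, breaks = breaks, plot = FALSE)
}

## ---------------------------------------------------------------------------
## Bimodality splitting

#' Split a (possibly) bimodal sample at the inter-peak minimum
#'
#' Smooths the sample on a log1p scale with a kernel density estimate,
#' finds the two largest local maxima, locates the density minimum
#' between them, splits the sample there and reports the mean and weight
#' of each part.  A sample without two separated peaks degrades
#' gracefully to a single mode.
#'
#' @param x Numeric sample (e.g. endpoint protein counts).
#' @param bw Bandwidth for [stats::density()] on the log1p scale,
#'   default `"SJ"` with fallback to `"nrd0"`.
#' @param min_sep Minimum ratio between the peak density and the valley
#'   density for a split to be accepted, default 1.2 (guards against
#'   splitting on sampling ripple).
#' @return A list with `n_modes` (1 or 2), `means`, `weights`,
#'   `split_point` (NA for unimodal input), and `mode_positions` (the
#'   density peak locations, original scale).
#' @export
split_bimodal <- function(x, bw = "SJ", min_sep = 1.2) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("empty sample")
  one_mode <- function() list(n_modes = 1L, means = mean(x), weights = 1,
                              split_point = NA_real_,
                              mode_positions = exp(mean(log1p(x))) - 1)
  if (length(unique(x)) < 3) return(one_mode())
  z <- log1p(x)
  d <- tryCatch(density(z, bw = bw), error = function(e) density(z))
  y <- d$y
  ## interior local maxima
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(locmax) < 2) return(one_mode())
  top2 <- locmax[order(y[locmax], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  if (min(y[lo], y[hi]) < min_sep * y[valley]) return(one_mode())
  split_z <- d$x[valley]
  split_point <- expm1(split_z)
  left <- x[log1p(x) <= split_z]
  right <- x[log1p(x) > split_z]
  list(n_modes = 2L,
       means = c(mean(left), mean(right)),
       weights = c(length(left), length(right)) / length(x),
       split_point = split_point,
       mode_positions = expm1(d$x[sort(top2)]))
}

## ---------------------------------------------------------------------------
## Adaptation times

#' Adaptation (first-passage) times of an ensemble
#'
#' First time each run's protein count reaches a threshold fraction
#' (default 90%) of its value at the upper stable fixed point.  Runs
#' that never cross within the horizon are reported as censored, not
#' dropped.
#'
#' The ensemble must either have been run with a matching first-passage
#' monitor (see [run_ensemble()]) or contain recorded trajectories from
#' which the crossing is read at the sampling resolution.
#'
#' @param ensemble An `xap_ensemble`.
#' @param reference_count Protein count at the upper fixed point (e.g.
#'   `conc_to_counts(fp$p_a[3], geom)`).
#' @param threshold Threshold fraction in (0, 1], default 0.9.  A
#'   threshold of 0 gives time 0 for every run.
#' @param species Species monitored, default `"P"`.
#' @param gamma_p Protein decay rate (1/s) for the seconds column.
#' @return A data frame with columns `run`, `tau`, `t_seconds`,
#'   `censored`; attribute `"threshold_count"`.
#' @export
adaptation_times <- function(ensemble, reference_count, threshold = 0.9,
                             species = "P", gamma_p = 5e-4) {
  stopifnot(inherits(ensemble, "xap_ensemble"))
  if (length(reference_count) != 1 || !is.finite(reference_count) ||
      reference_count <= 0)
    stop("'reference_count' must be a positive number (upper fixed ",
         "point protein count)")
  if (threshold < 0 || threshold > 1)
    stop("'threshold' must lie in [0, 1]")
  thr <- threshold * reference_count
  n <- nrow(ensemble$endpoints)
  if (threshold == 0) {
    tau <- rep(0, n)
  } else if (!is.null(ensemble$monitor_species) &&
             ensemble$monitor_species == species &&
             isTRUE(all.equal(ensemble$monitor_value, thr))) {
    tau <- ensemble$first_passage
  } else if (!is.null(ensemble$trajectories)) {
    tau <- vapply(ensemble$trajectories, function(tr) {
      i <- which(tr[[species]] >= thr)
      if (length(i) == 0) NA_real_ else tr$tau[min(i)]
    }, numeric(1))
  } else {
    stop("ensemble carries neither a matching first-passage monitor ",
         "nor trajectories; rerun with monitor_species = '", species,
         "' and monitor_value = threshold * reference_count")
  }
  out <- data.frame(run = seq_len(n), tau = tau,
                    t_seconds = tau / gamma_p, censored = is.na(tau))
  attr(out, "threshold_count") <- thr
  out
}

#' Deterministic adaptation time
#'
#' Crossing time of the deterministic trajectory (from a given initial
#' state, default the origin) through the threshold fraction of the
#' upper-fixed-point protein level.
#'
#' @param params An [xap_params()] object.
#' @param upper_p_a Protein level of the upper stable fixed point
#'   (nondimensional).
#' @param threshold Threshold fraction, default 0.9.
#' @param initial Initial state, default the origin.
#' @param tau_end Integration horizon, default 500.
#' @param variant Optional [circuit_variant()].
#' @param gamma_p Protein decay rate (1/s) for the seconds value.
#' @return A list with `tau` and `t_seconds` (NA if never crossed).
#' @export
deterministic_adaptation_time <- function(params, upper_p_a, threshold = 0.9,
                                          initial = c(0, 0, 0),
                                          tau_end = 500, variant = NULL,
                                          gamma_p = 5e-4) {
  tr <- integrate_trajectory(params, initial, tau_end, variant,
                             n_out = 4000, gamma_p = gamma_p)
  i <- which(tr$p_a >= threshold * upper_p_a)
  if (length(i) == 0) return(list(tau = NA_real_, t_seconds = NA_real_))
  ## linear interpolation inside the bracketing output step
  i <- min(i)
  if (i == 1) return(list(tau = 0, t_seconds = 0))
  t0 <- tr$tau[i - 1]; t1 <- tr$tau[i]
  p0 <- tr$p_a[i - 1]; p1 <- tr$p_a[i]
  tau <- t0 + (threshold * upper_p_a - p0) / (p1 - p0) * (t1 - t0)
  list(tau = tau, t_seconds = tau / gamma_p)
}

## ---------------------------------------------------------------------------
## Hysteresis protocol

#' Stochastic hysteresis protocol
#'
#' For each extracellular inducer concentration on a grid, runs two
#' ensembles: one initialized at zero counts (naive cells) and one at
#' the counts of the upper deterministic fixed point (induced cells;
#' rounded half-up).  Inside the bistable window the two branch means
#' disagree, tracing the hysteresis loop; grid points without an upper
#' fixed point are marked inapplicable for the induced branch.
#'
#' @param params An [xap_params()] object (its `c_a` is replaced per
#'   grid value).
#' @param c_grid Positive vector of extracellular concentrations.
#' @param geom A [cell_geometry()] object.
#' @param n_runs Runs per ensemble per grid point.
#' @param t_end Horizon per run (units of 1/gamma_p).
#' @param base_seed RNG seed base; each (grid point, branch, run) gets a
#'   distinct seed.
#' @param variant Optional [circuit_variant()].
#' @param algorithm `"hybrid"` (default) or `"direct"`.
#' @param ... Further simulator arguments.
#' @return An object of class `xap_hysteresis`: a data frame with one
#'   row per grid point and columns `c_a`, `n_fixed_points`,
#'   `det_low_P`, `det_high_P` (deterministic fixed-point protein
#'   counts, NA where absent), `zero_mean_P`, `upper_mean_P` (branch
#'   ensemble means; NA where inapplicable), plus split-mode summaries
#'   `zero_modes`, `upper_modes` in an attribute `"splits"`.
#' @export
hysteresis_protocol <- function(params, c_grid, geom = cell_geometry(),
                                n_runs = 50, t_end = 500, base_seed = 1,
                                variant = NULL,
                                algorithm = c("hybrid", "direct"), ...) {
  algorithm <- match.arg(algorithm)
  variant <- .check_variant(variant)
  stopifnot(all(c_grid > 0))
  rows <- vector("list", length(c_grid))
  splits <- vector("list", length(c_grid))
  for (i in seq_along(c_grid)) {
    p_i <- update_params(params, c_a = c_grid[i])
    fp <- find_fixed_points(p_i, variant)
    stab <- fp[fp$stability == "stable", , drop = FALSE]
    low_P <- if (nrow(stab) >= 1) conc_to_counts(min(stab$p_a), geom)
             else NA_real_
    high_P <- if (nrow(stab) >= 2) conc_to_counts(max(stab$p_a), geom)
              else NA_real_
    net <- build_network(p_i, geom, variant)
    seed_i <- base_seed + 2000L * (i - 1L)
    ens0 <- run_ensemble(net, c(0, 0, 0), t_end, n_runs,
                         base_seed = seed_i, algorithm = algorithm, ...)
    zero_mean <- mean(ens0$endpoints[, "P"])
    split0 <- split_bimodal(ens0$endpoints[, "P"])
    upper_mean <- NA_real_; split1 <- NULL
    ## the induced branch starts at the highest stable fixed point; a
    ## grid point with no stable state is marked inapplicable (NA)
    if (nrow(stab) >= 1) {
      top <- stab[nrow(stab), ]
      init1 <- conc_to_counts(c(top$m_a, top$p_a, top$x_a), geom)
      ens1 <- run_ensemble(net, init1, t_end, n_runs,
                           base_seed = seed_i + 1000L,
                           algorithm = algorithm, ...)
      upper_mean <- mean(ens1$endpoints[, "P"])
      split1 <- split_bimodal(ens1$endpoints[, "P"])
    }
    rows[[i]] <- data.frame(c_a = c_grid[i], n_fixed_points = nrow(fp),
                            det_low_P = low_P, det_high_P = high_P,
                            zero_mean_P = zero_mean,
                            upper_mean_P = upper_mean)
    splits[[i]] <- list(zero = split0, upper = split1)
  }
  out <- do.call(rbind, rows)
  attr(out, "splits") <- splits
  class(out) <- c("xap_hysteresis", "data.frame")
  out
}
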