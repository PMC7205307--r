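test_that("the switch network recovers the macroscopic rate equations in
           expectation", {
  net <- build_network(ref_params, ref_geom)
  Om <- ref_geom$Omega
  ## at zero counts only transcription and non-specific influx can fire
  a0 <- network_propensities(net, c(0, 0, 0))
  expect_true(all(a0[c("transcription", "nup_influx")] > 0))
  expect_true(all(a0[setdiff(names(a0),
                             c("transcription", "nup_influx"))] == 0))
  ## without protein every transporter/enzyme channel is silent
  aP0 <- network_propensities(net, c(3, 0, 1e5))
  expect_equal(unname(aP0[c("xapB_import", "xapB_export",
                            "xapA_degradation")]), c(0, 0, 0))
  ## mean-field consistency: stoich %*% a == Omega * rhs at matched
  ## concentrations
  sts <- random_states(20, seed = 13)
  for (i in seq_len(nrow(sts))) {
    counts <- as.numeric(sts[i, ]) * Om
    a <- network_propensities(net, counts)
    drift <- as.numeric(net$stoich %*% a)
    macro <- Om * xap_rhs(as.numeric(sts[i, ]), ref_params)
    expect_equal(drift, macro, tolerance = 1e-10)
  }
  ## variant flags drop the matching channels
  netB <- build_network(ref_params, ref_geom,
                        variant = circuit_variant(xapB_removed = TRUE))
  nm <- vapply(netB$reactions, `[[`, "", "name")
  expect_false(any(grepl("xapB", nm)))
})

test_that("the direct method reproduces the Poisson birth-death
           stationary law and is seed-deterministic", {
  net <- birth_death_network(birth = 20, death = 1)
  ends <- vapply(1:1500, function(i)
    simulate_direct(net, 0, 12, seed = 1000 + i)$final, numeric(1))
  expect_gt(poisson_gof_pvalue(as.integer(ends), 20), 1e-3)
  ## identical seed, identical trajectory
  rt <- seq(0, 12, by = 0.5)
  s1 <- simulate_direct(net, 0, 12, seed = 99, record_times = rt)
  s2 <- simulate_direct(net, 0, 12, seed = 99, record_times = rt)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$final, s2$final)
  ## a zero-propensity network never moves
  dead <- reaction_network("A", matrix(1L, 1, 1),
                           list(list(type = "constant", rate = 0)))
  expect_equal(unname(simulate_direct(dead, 5, 100, seed = 1)$final), 5)
})

test_that("hybrid tau-leaping agrees with the exact method in
           distribution", {
  ## low-copy system with thresholds low enough that leaping really runs
  net <- birth_death_network(birth = 500, death = 10)
  n <- 800
  e_dir <- vapply(1:n, function(i)
    simulate_direct(net, 0, 2, seed = 2000 + i)$final, numeric(1))
  e_hyb <- vapply(1:n, function(i)
    simulate_hybrid(net, 0, 2, seed = 7000 + i,
                    count_thresh = 20, rate_thresh = 50)$final, numeric(1))
  ks <- suppressWarnings(stats::ks.test(e_dir, e_hyb))
  expect_gt(ks$p.value, 0.01)
  ## means agree within Monte-Carlo error
  expect_lt(abs(mean(e_dir) - mean(e_hyb)),
            4 * sqrt(var(e_dir) / n + var(e_hyb) / n))
})

test_that("counts stay nonnegative and truncation is flagged, not
           silent", {
  net <- build_network(update_params(ref_params, c_a = 25), ref_geom)
  s <- simulate_direct(net, c(0, 0, 0), 250, seed = 3, max_events = 2e5)
  expect_true(s$truncated)
  expect_lt(s$t_final, 250)
  expect_true(all(s$final >= 0))
  ## the hybrid scheme finishes the same horizon
  h <- simulate_hybrid(net, c(0, 0, 0), 250, seed = 3)
  expect_equal(h$status, 0)
  expect_equal(h$t_final, 250)
  expect_true(all(h$final >= 0))
  ## and lands near the upper fixed point
  fp <- find_fixed_points(update_params(ref_params, c_a = 25))
  upX <- conc_to_counts(fp$x_a[nrow(fp)], ref_geom)
  expect_gt(h$final[["X"]], upX / 3)
  expect_lt(h$final[["X"]], upX * 3)
})

test_that("geometric bursts preserve the mean and inflate the Fano
           factor", {
  ## constitutive birth-death, burst mean 5: stationary mean unchanged at
  ## birth*b/death, variance super-Poissonian
  net_b <- birth_death_network(birth = 10, death = 1, burst_mean = 5)
  ends <- vapply(1:600, function(i)
    simulate_direct(net_b, 0, 12, seed = 4000 + i)$final, numeric(1))
  expect_lt(abs(mean(ends) - 50) / 50, 0.15)
  expect_gt(var(ends) / mean(ends), 2)
  ## burst declaration is validated
  expect_error(reaction_network("A", matrix(c(-1L), 1, 1),
    list(list(type = "linear", rate = 1, scale_sp = "A", burst_mean = 3))),
    "product")
})

test_that("ensembles are reproducible and keep failed runs visible", {
  net <- birth_death_network(birth = 20, death = 1)
  e1 <- run_ensemble(net, 0, 5, 20, base_seed = 7, algorithm = "direct")
  e2 <- run_ensemble(net, 0, 5, 20, base_seed = 7, algorithm = "direct")
  expect_identical(e1$endpoints, e2$endpoints)
  expect_equal(e1$seeds, 7 + 0:19)
  expect_warning(
    run_ensemble(net, 0, 5, 5, base_seed = 7, algorithm = "direct",
                 max_events = 10),
    "truncated")
})

test_that("bimodal samples are split at the inter-peak minimum", {
  set.seed(31)
  x <- c(pmax(rnorm(6000, 5, 1.5), 0), rnorm(4000, 500, 60))
  sp <- split_bimodal(x)
  expect_equal(sp$n_modes, 2L)
  expect_lt(abs(sp$means[1] - 5) / 5, 0.05)
  expect_lt(abs(sp$means[2] - 500) / 500, 0.05)
  ## weights recovered within 3 sigma of the binomial error
  se_w <- sqrt(0.6 * 0.4 / 10000)
  expect_lt(abs(sp$weights[1] - 0.6), 3 * se_w)
  expect_gt(sp$split_point, sp$means[1]); expect_lt(sp$split_point, sp$means[2])
  ## a single Gaussian yields one mode and no split point
  sp1 <- split_bimodal(rnorm(5000, 100, 10))
  expect_equal(sp1$n_modes, 1L)
  expect_true(is.na(sp1$split_point))
  ## degenerate constant sample
  sp0 <- split_bimodal(rep(3, 50))
  expect_equal(sp0$n_modes, 1L)
  expect_equal(sp0$means, 3)
})

test_that("adaptation times degrade to zero threshold and censor
           non-crossers", {
  net <- birth_death_network(birth = 2, death = 1)
  ens <- run_ensemble(net, 0, 3, 30, base_seed = 2, algorithm = "direct",
                      monitor_species = "A", monitor_value = 0.9 * 100)
  at <- adaptation_times(ens, reference_count = 100, threshold = 0.9,
                         species = "A")
  expect_true(all(at$censored))  # mean 2: the threshold 90 is unreachable
  at0 <- adaptation_times(ens, reference_count = 100, threshold = 0,
                          species = "A")
  expect_true(all(at0$tau == 0))
  expect_error(adaptation_times(ens, reference_count = -1), "positive")
  ## trajectory-based crossing detection agrees with the monitor
  rt <- seq(0, 20, by = 0.05)
  net2 <- birth_death_network(birth = 50, death = 1)
  ens2 <- run_ensemble(net2, 0, 20, 15, base_seed = 5, algorithm = "direct",
                       record_times = rt,
                       monitor_species = "A", monitor_value = 45)
  at_mon <- adaptation_times(ens2, reference_count = 50, threshold = 0.9,
                             species = "A")
  ens2_nomon <- ens2
  ens2_nomon$monitor_species <- NULL
  at_trj <- adaptation_times(ens2_nomon, reference_count = 50,
                             threshold = 0.9, species = "A")
  expect_false(any(at_mon$censored))
  expect_equal(at_trj$tau, at_mon$tau, tolerance = 0.06)
})
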