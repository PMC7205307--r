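test_that("the default variant is a strict identity on the rate laws", {
  v <- circuit_variant()
  x <- 10^seq(-3, 4, length.out = 40)
  expect_identical(promoter_activity(x, ref_params, v),
                   promoter_activity(x, ref_params))
  sts <- random_states(10, seed = 9)
  for (i in seq_len(nrow(sts))) {
    st <- as.numeric(sts[i, ])
    expect_identical(xap_rhs(st, ref_params, v), xap_rhs(st, ref_params))
  }
})

test_that("variant construction rejects contradictory settings", {
  expect_error(circuit_variant(promoter_sites = 3), "promoter_sites")
  expect_error(circuit_variant(promoter_sites = 1, deps_coop_override = 2),
               "contradictory")
  expect_error(circuit_variant(active_policy = "everything"), "arg")
})

test_that("reduced-cooperativity scenarios reproduce the ablation study", {
  sc <- fixture_scenarios()
  ## one inducer site, compensated rho and c_a: still bistable
  fa <- find_fixed_points(sc$fig8a$params, sc$fig8a$variant)
  expect_equal(nrow(fa), 3L)
  ## one promoter site, compensated: still bistable
  fb <- find_fixed_points(sc$fig8b$params, sc$fig8b$variant)
  expect_equal(nrow(fb), 3L)
  ## no cooperativity anywhere: monostable for every tested c_a
  for (ca in c(1, 3, 6, 13, 50, 200)) {
    fc <- find_fixed_points(update_params(sc$fig8c$params, c_a = ca),
                            sc$fig8c$variant)
    expect_equal(nrow(fc), 1L)
  }
})

test_that("no joint parameter draw yields bistability once all
           cooperativity is removed", {
  ## 100 log-uniform draws across the estimated parameter ranges, with a
  ## single binding site in both components
  set.seed(42)
  vnc <- circuit_variant(inducer_sites = 1, promoter_sites = 1)
  lu <- function(mid, half) 10^runif(1, mid - half, mid + half)
  n_multi <- 0L
  for (i in 1:100) {
    K_IA <- lu(2, 1)
    pars <- xap_params(
      rho_m = lu(-3, 2), gamma_mp = lu(1, 0.5), rho_p = lu(2, 0.5),
      XapR_R = lu(0, 2), c_a = lu(1, 2),
      k_beta_i = lu(4, 1), k_beta_e = lu(3, 2), k_alpha = lu(2, 0.8),
      k_eta = lu(0, 3), xi = runif(1, 0.7, 0.9),
      K_beta_i = lu(1, 2), K_beta_e = lu(2, 2),
      K_chiA = lu(2, 1), K_IA = K_IA,
      deps_x = runif(1, 2, 2 * (log(K_IA) - 1)), deps_coop = 0)
    nfp <- suppressWarnings(nrow(find_fixed_points(pars, vnc)))
    if (nfp >= 3L) n_multi <- n_multi + 1L
  }
  expect_equal(n_multi, 0L)
})

test_that("the any-bound activity policy preserves bistability in a
           shifted window", {
  va <- circuit_variant(active_policy = "any_xapr_bound")
  br <- bistable_range(ref_params, "c_a", c(1, 100), variant = va,
                       n_scan = 40)
  expect_true(br$bistable_anywhere)
  ## the policy only adds active states, so activity never decreases
  x <- 10^seq(-2, 4, length.out = 60)
  expect_true(all(promoter_activity(x, ref_params, va) >=
                  promoter_activity(x, ref_params)))
})

test_that("cooperativity sweep reports the fixed-point structure per
           energy", {
  sw <- cooperativity_sweep(ref_params, c(0, 5))
  expect_equal(sw$deps_coop, c(0, 5))
  expect_equal(sw$n_fixed_points[2], 3L)
  ## a single-value sweep reduces to find_fixed_points with an override
  sw1 <- cooperativity_sweep(ref_params, 5)
  expect_equal(sw1$n_fixed_points,
               nrow(find_fixed_points(ref_params)))
  fp_over <- attr(sw1, "fixed_points")[[1]]
  expect_equal(fp_over$x_a, find_fixed_points(ref_params)$x_a,
               tolerance = 1e-9)
  expect_error(cooperativity_sweep(ref_params, 0:2,
                                   circuit_variant(promoter_sites = 1)),
               "single-site")
})
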