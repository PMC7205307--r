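test_that("MWC active fraction matches its closed-form limits", {
  p <- ref_params  # K_chiA = 100, K_IA = 100, deps_x = 5
  ## zero inducer: leak level 1/(1 + e^deps_x)
  expect_equal(xapr_active_fraction(0, p), 1 / (1 + exp(5)),
               tolerance = 1e-12)
  ## saturation: 1/(1 + e^deps_x / K_IA^2), probed at x = 1e10
  expect_equal(xapr_active_fraction(1e10, p),
               1 / (1 + exp(5) / 100^2), tolerance = 1e-6)
  ## single-site variant changes the exponents
  v1 <- circuit_variant(inducer_sites = 1)
  expect_equal(xapr_active_fraction(1e10, p, v1),
               1 / (1 + exp(5) / 100), tolerance = 1e-6)
  expect_error(xapr_active_fraction(-1, p), "nonnegative")
})

test_that("MWC active fraction is a monotone switch bounded in (0,1)", {
  p <- ref_params
  x <- 10^seq(-3, 6, length.out = 300)
  f <- xapr_active_fraction(x, p)
  expect_true(all(f > 0 & f < 1))
  expect_true(all(diff(f) > 0))  # K_xA < K_xI: induction is monotone
})

test_that("promoter state weights carry the factorized partition function", {
  ## no activator: only the empty and polymerase states have weight
  expect_equal(unname(promoter_state_weights(0, 1, 5)),
               c(1, 0, 0, 0, 1, 0, 0, 0))
  ## unit ratios, no polymerase, no cooperativity
  expect_equal(unname(promoter_state_weights(1, 0, 0)),
               c(1, 1, 1, 1, 0, 0, 0, 0))
  ## sum equals (1 + q)(1 + 2r + r^2 e^coop) for arbitrary inputs
  set.seed(7)
  for (i in 1:25) {
    r <- 10^runif(1, -3, 3); q <- 10^runif(1, -3, 3)
    dc <- runif(1, -2, 8)
    w <- promoter_state_weights(r, q, dc)
    expect_equal(sum(w), (1 + q) * (1 + 2 * r + r^2 * exp(dc)),
                 tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("promoter active probability has the right limits and identities", {
  p <- ref_params
  expect_equal(promoter_active_probability(0, p), 0)
  ## saturation limit is pol_term
  expect_equal(promoter_active_probability(1e12, p), 1, tolerance = 1e-9)
  expect_equal(promoter_active_probability(1e12, p, pol_term = 0.4), 0.4,
               tolerance = 1e-9)
  ## without cooperativity the two-site formula collapses to (r/(1+r))^2
  p0 <- update_params(ref_params, deps_coop = 0)
  for (r in c(0.1, 1, 10))
    expect_equal(promoter_active_probability(r, p0),
                 (r / (1 + r))^2, tolerance = 1e-12)
  ## monotone nondecreasing in the activator, bounded in [0, 1)
  r <- 10^seq(-4, 6, length.out = 200)
  pr <- promoter_active_probability(r, p)
  expect_true(all(diff(pr) >= 0))
  expect_true(all(pr >= 0 & pr < 1))
})

test_that("variant policies reshape the active probability as specified", {
  p <- ref_params
  v1 <- circuit_variant(promoter_sites = 1)
  for (r in c(0.2, 1, 5))
    expect_equal(promoter_active_probability(r, p, v1), r / (1 + r),
                 tolerance = 1e-12)
  ## any-bound policy counts singly occupied states too: strictly larger
  ## than the fully-occupied policy for intermediate occupancy
  va <- circuit_variant(active_policy = "any_xapr_bound")
  r <- c(0.01, 0.1, 1)
  expect_true(all(promoter_active_probability(r, p, va) >
                  promoter_active_probability(r, p)))
  E <- exp(5)
  expect_equal(promoter_active_probability(0.5, p, va),
               (2 * 0.5 + 0.25 * E) / (1 + 2 * 0.5 + 0.25 * E),
               tolerance = 1e-12)
})

test_that("mean mRNA follows (rho_m/gamma_mp) * activity with ceiling 1e-4", {
  p <- ref_params
  x <- c(0, 1, 50, 1e3)
  expect_equal(mean_mrna(x, p),
               p$rho_m / p$gamma_mp * promoter_activity(x, p))
  ## at full activation the ceiling is rho_m / gamma_mp = 1e-4
  sat <- update_params(ref_params, XapR_R = 1e9)
  expect_equal(mean_mrna(1e9, sat), 1e-4, tolerance = 1e-6)
  expect_equal(mean_mrna(0, update_params(p, deps_x = 60)), 0,
               tolerance = 1e-20)  # no activity, no transcript
})
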