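test_that("the reference configuration has the bistable three-point
           structure", {
  fp <- find_fixed_points(ref_params)
  expect_equal(nrow(fp), 3L)
  expect_equal(fp$stability, c("stable", "unstable", "stable"))
  ## lower/middle/upper are ordered simultaneously in all coordinates
  expect_true(all(diff(fp$m_a) > 0))
  expect_true(all(diff(fp$p_a) > 0))
  expect_true(all(diff(fp$x_a) > 0))
  ## steady-state consistency: m_a equals the analytic mean mRNA and the
  ## full right-hand side vanishes
  expect_equal(fp$m_a, mean_mrna(fp$x_a, ref_params), tolerance = 1e-9)
  for (i in 1:3) {
    r <- xap_rhs(as.numeric(fp[i, c("m_a", "p_a", "x_a")]), ref_params)
    expect_lt(max(abs(r)) / max(fp$x_a[i], 1), 1e-8)
  }
  ## the unstable middle point has an eigenvalue with positive real part
  eig <- attr(fp, "eigenvalues")[[2]]
  expect_gt(max(Re(eig)), 0)
  ## no two roots within relative 1e-6
  expect_true(all(diff(fp$x_a) / fp$x_a[-1] > 1e-6))
})

test_that("a brute-force sign sweep finds the same root brackets as the
           solver", {
  ## independent oracle: dense evaluation of the scalar steady-state
  ## function; the solver must find exactly one root per sign change
  for (ca in c(7, 13, 25, 40)) {
    p <- update_params(ref_params, c_a = ca)
    xs <- 10^seq(-6, 8, length.out = 1e5)
    gs <- xapswitch:::steady_state_residual(xs, p)
    n_brackets <- sum(gs[-1] * gs[-length(gs)] < 0)
    expect_equal(nrow(find_fixed_points(p)), n_brackets)
  }
})

test_that("off-window concentrations are monostable on the expected branch", {
  fp13 <- find_fixed_points(ref_params)
  fp7 <- find_fixed_points(update_params(ref_params, c_a = 7))
  expect_equal(nrow(fp7), 1L)
  expect_equal(fp7$stability, "stable")
  expect_lt(fp7$p_a, fp13$p_a[2])   # low-expression branch
  fp40 <- find_fixed_points(update_params(ref_params, c_a = 40))
  expect_equal(nrow(fp40), 1L)
  expect_gt(fp40$p_a, fp13$p_a[2])  # high-expression branch
})

test_that("the 2D mRNA quasi-steady-state reduction preserves fixed points
           and stability", {
  red <- reduce_mrna_qss(ref_params)
  fp <- find_fixed_points(ref_params)
  for (i in seq_len(nrow(fp))) {
    st2 <- c(fp$p_a[i], fp$x_a[i])
    expect_lt(max(abs(red$rhs(st2))), 1e-10 * max(1, fp$x_a[i]))
    eig2 <- eigen(red$jacobian(st2), only.values = TRUE)$values
    stab2 <- if (all(Re(eig2) < 0)) "stable" else "unstable"
    expect_equal(stab2, fp$stability[i])
  }
  ## reduced protein nullcline is rho * p_active(x_a)
  x <- 10^seq(-2, 4, length.out = 50)
  expect_equal(red$protein_nullcline(x),
               ref_params$rho * promoter_activity(x, ref_params),
               tolerance = 1e-14)
  ## the eliminated mRNA level matches the analytic mean
  expect_equal(red$mrna_qss(x), mean_mrna(x, ref_params), tolerance = 1e-14)
})

test_that("trajectories settle on the basin-matching stable state without
           oscillation", {
  ## monostable high: the origin flows to the unique high fixed point
  p40 <- update_params(ref_params, c_a = 40)
  fp40 <- find_fixed_points(p40)
  tr <- integrate_trajectory(p40, c(0, 0, 0), 400)
  end <- tr[nrow(tr), ]
  expect_equal(end$p_a, fp40$p_a, tolerance = 1e-4)
  expect_equal(end$x_a, fp40$x_a, tolerance = 1e-4)
  ## bistable: the origin lies in the basin of the LOW state
  fp13 <- find_fixed_points(ref_params)
  tr13 <- integrate_trajectory(ref_params, c(0, 0, 0), 400)
  expect_equal(tr13$p_a[nrow(tr13)], fp13$p_a[1], tolerance = 1e-4)
  ## non-oscillatory approach: after the initial transient the protein
  ## derivative changes sign at most once
  dp <- diff(tr$p_a[tr$tau > 5])
  sign_changes <- sum(diff(sign(dp[dp != 0])) != 0)
  expect_lte(sign_changes, 1)
  ## all states remain nonnegative
  expect_true(all(tr$m_a >= 0 & tr$p_a >= 0 & tr$x_a >= 0))
})

test_that("long integrations from random starts are trapped by the stable
           fixed points", {
  fp <- find_fixed_points(ref_params)
  targets <- fp$p_a[fp$stability == "stable"]
  set.seed(23)
  for (i in 1:12) {
    init <- c(10^runif(1, -7, -3.5), 10^runif(1, -5, -1), 10^runif(1, -2, 3))
    tr <- integrate_trajectory(ref_params, init, 400, n_out = 200)
    endp <- tr$p_a[nrow(tr)]
    expect_lt(min(abs(endp - targets) / targets), 1e-3)
  }
})

test_that("the bifurcation diagram over c_a shows the 1-3-1 branch pattern
           with folds bracketing the window", {
  vals <- 10^seq(0, 2, length.out = 41)
  bd <- bifurcation_diagram(ref_params, "c_a", vals)
  counts <- attr(bd, "counts")
  rle_c <- rle(counts)$values
  expect_equal(rle_c, c(1L, 3L, 1L))
  folds <- attr(bd, "folds")
  expect_length(folds, 2L)
  expect_gt(folds[1], 7); expect_lt(folds[1], 12)
  expect_gt(folds[2], 18.5); expect_lt(folds[2], 25)
  ## the window contains the reference and ensemble concentrations
  n_at <- function(ca) nrow(find_fixed_points(update_params(ref_params,
                                                            c_a = ca)))
  expect_equal(n_at(12), 3L)
  expect_equal(n_at(18.5), 3L)
  expect_equal(n_at(25), 1L)
  ## a one-point grid degenerates to a single column
  bd1 <- bifurcation_diagram(ref_params, "c_a", 13)
  expect_equal(unique(bd1$control_value), 13)
  expect_equal(nrow(bd1), 3L)
})

test_that("bistable_range recovers the same window boundaries by bisection", {
  vals <- 10^seq(0, 2, length.out = 41)
  bd <- bifurcation_diagram(ref_params, "c_a", vals)
  br <- bistable_range(ref_params, "c_a", c(1, 100))
  expect_true(br$bistable_anywhere)
  expect_length(br$critical, 2L)
  expect_equal(sort(br$critical), sort(attr(bd, "folds")), tolerance = 5e-3)
  ## monostable throughout when the transporter is removed
  expect_message(
    brB <- bistable_range(ref_params, "c_a", c(1, 100),
                          variant = circuit_variant(xapB_removed = TRUE)),
    "no bistable region")
  expect_false(brB$bistable_anywhere)
})
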