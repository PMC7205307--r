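test_that("bundled scenarios are valid and carry the study settings", {
  sc <- fixture_scenarios()
  expect_true(all(vapply(sc, inherits, logical(1), "xap_scenario")))
  expect_equal(sc$fig5_bistable$params$c_a, 13)
  expect_equal(sc$fig6a$params$c_a, 7)
  expect_equal(sc$fig6b$params$c_a, 40)
  expect_true(sc$fig7a$variant$xapA_removed)
  expect_true(sc$fig7b$variant$xapB_removed)
  expect_equal(sc$fig8a$params$rho, 0.07, tolerance = 1e-12)
  expect_equal(sc$fig8b$params$rho, 0.13, tolerance = 1e-12)
  expect_equal(sc$fig8c$params$XapR_R, 5)
  expect_equal(sc$fig9a$params$c_a, 12)
  expect_equal(sc$fig9b$params$c_a, 18.5)
  expect_equal(sc$fig9c$params$c_a, 25)
  expect_equal(sc$fig10$horizon_s, 5e5)
  expect_gt(length(attr(sc$fig11, "c_grid")), 5)
})

test_that("configs load with defaults, overrides and exhaustive
           validation", {
  ## an empty config is the reference scenario
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  sc <- load_config(f)
  expect_equal(sc$params$c_a, 13)
  expect_equal(unclass(sc$variant), unclass(circuit_variant()))
  ## a single override leaves every other field at its default
  writeLines("c_a: 18.5", f)
  sc2 <- load_config(f)
  expect_equal(sc2$params$c_a, 18.5)
  expect_equal(sc2$params$rho_m, 1e-3)
  ## schema violations are listed exhaustively with field names
  writeLines(c("k_alpha: -2", "frobnicate: 1", "variant:",
               "  promoter_sites: 7"), f)
  err <- tryCatch(load_config(f), error = identity)
  expect_match(conditionMessage(err), "k_alpha")
  expect_match(conditionMessage(err), "frobnicate")
  expect_match(conditionMessage(err), "promoter_sites")
})

test_that("scenarios round-trip through config files unchanged", {
  sc <- fixture_scenarios()$fig8a
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_config(sc, f)
    back <- load_config(f)
    flds <- xapswitch:::.NONDIM_FIELDS
    expect_equal(unclass(back$params)[flds], unclass(sc$params)[flds],
                 tolerance = 1e-15)
    expect_equal(unclass(back$variant), unclass(sc$variant))
    expect_equal(back$horizon_s, sc$horizon_s)
    expect_equal(back$geom$Omega, sc$geom$Omega)
  }
})

test_that("result writing is faithful and hash-stable", {
  dir <- withr::local_tempdir()
  fp <- find_fixed_points(ref_params)
  man1 <- write_results(list(fixed_points = as.data.frame(fp)), dir,
                        scenario = fixture_scenarios()$fig5_bistable,
                        seeds = 1:3)
  back <- read.csv(file.path(dir, "fixed_points.csv"))
  expect_equal(back$p_a, fp$p_a, tolerance = 1e-12)
  expect_equal(back$stability, fp$stability)
  ## unchanged content, unchanged hash; changed content, changed hash
  man2 <- write_results(list(fixed_points = as.data.frame(fp)), dir)
  expect_identical(man1$files[[1]]$md5, man2$files[[1]]$md5)
  fp2 <- as.data.frame(fp); fp2$p_a[1] <- fp2$p_a[1] * 2
  man3 <- write_results(list(fixed_points = fp2), dir)
  expect_false(identical(man1$files[[1]]$md5, man3$files[[1]]$md5))
})

test_that("a rerun with the same seed yields byte-identical trajectory
           files", {
  dir <- withr::local_tempdir()
  net <- birth_death_network(birth = 30, death = 1)
  rt <- seq(0, 10, by = 0.1)
  h <- character(2)
  for (k in 1:2) {
    s <- simulate_direct(net, 0, 10, seed = 42, record_times = rt)
    write_results(list(trajectory = s$trajectory),
                  file.path(dir, paste0("run", k)))
    h[k] <- unname(tools::md5sum(file.path(dir, paste0("run", k),
                                           "trajectory.csv")))
  }
  expect_identical(h[1], h[2])
})

test_that("the hysteresis protocol separates branches inside the window
           and merges them below it", {
  res <- hysteresis_protocol(ref_params, c_grid = c(7, 13),
                             geom = ref_geom, n_runs = 15, t_end = 150,
                             base_seed = 21)
  expect_s3_class(res, "xap_hysteresis")
  ## below the window both initializations settle low
  below <- res[res$c_a == 7, ]
  expect_equal(below$n_fixed_points, 1L)
  expect_lt(below$zero_mean_P, 20)
  expect_lt(below$upper_mean_P, 20)
  ## inside the window the branches disagree, straddling the unstable one
  inside <- res[res$c_a == 13, ]
  expect_equal(inside$n_fixed_points, 3L)
  fp <- find_fixed_points(ref_params)
  mid <- conc_to_counts(fp$p_a[2], ref_geom)
  expect_lt(inside$zero_mean_P, mid)
  expect_gt(inside$upper_mean_P, mid)
})
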