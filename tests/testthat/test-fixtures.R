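test_that("default geometry carries the five middle-ear areas exactly", {
  g <- default_geometry()
  expect_identical(g$a_tm, 80e-6)
  expect_identical(g$a_ow, 5.1e-6)
  expect_identical(g$a_fp, 4.2e-6)
  expect_identical(g$a_rw, 2.3e-6)
  expect_identical(g$a_sh, 0.58e-6)
  expect_identical(g$probe_distance_ow, 200e-6)
  expect_gte(g$n_segments, 2L)
  expect_true(all(g$bm_width_profile > 0))
  expect_true(all(diff(g$bm_width_profile) >= 0))      # widens toward apex
  expect_true(all(diff(g$bm_thickness_profile) <= 0))  # thins toward apex
  # the areas survive any re-parameterisation of the grid
  for (n in c(2L, 17L, 250L)) {
    gn <- default_geometry(n_segments = n)
    expect_identical(gn$a_fp, 4.2e-6)
    expect_identical(gn$a_rw, 2.3e-6)
    expect_length(gn$bm_width_profile, n)
  }
  expect_error(default_geometry(n_segments = 1), ">= 2")
  expect_error(default_geometry(a_rw = 0), "positive")
  expect_error(default_geometry(bm_width_base = 6e-4, bm_width_apex = 1e-4),
               "nondecreasing")
})

test_that("default materials reproduce the baseline constitutive set", {
  mat <- default_materials()
  expect_equal(mat$bm$E_X, 2.0e6)
  expect_equal(mat$bm$E_Y, 2.0e4)
  expect_equal(mat$bm$E_Z, 2.0e6)
  expect_equal(mat$rwm$E, 5.0e6)
  expect_equal(mat$rwm$nu, 0.49)
  expect_equal(mat$fluid$rho, 1034)
  expect_equal(mat$fluid$mu, 0.0028)
  expect_equal(mat$damping$alpha, 100)
  expect_equal(mat$damping$beta, 6.43e-7)
  expect_equal(mat$damping$c, 5000)
})

test_that("scenario construction is total over the five names and rejects others", {
  sc <- make_scenario("sal_ossified")
  expect_equal(sc$sal_stiffness_mode, "ossified")
  expect_equal(sc$rwm_stiffness_mode, "normal")
  sc <- make_scenario("rwm_x100")
  expect_equal(sc$rwm_stiffness_mode, "x100")
  expect_equal(sc$sal_stiffness_mode, "normal")
  sc <- make_scenario("normal")
  expect_equal(sc$sal_stiffness_mode, "normal")
  expect_equal(sc$rwm_stiffness_mode, "normal")
  # exactly one window is touched in every pathological scenario
  for (name in c("sal_x100", "sal_ossified", "rwm_x100", "rwm_ossified")) {
    sc <- make_scenario(name)
    touched <- c(sc$sal_stiffness_mode, sc$rwm_stiffness_mode) != "normal"
    expect_equal(sum(touched), 1L)
  }
  err <- tryCatch(make_scenario("bilateral"), error = identity)
  expect_match(conditionMessage(err), "normal, sal_x100")
  expect_error(make_scenario(c("normal", "sal_x100")))
})

test_that("perturbation ensembles are seed-deterministic with unit-mean factors", {
  p <- list(E = 2e6, fluid = list(rho = 1034), label = "bm")
  # zero spread reproduces the base exactly
  same <- perturb_ensemble(p, 5, 0.0, seed = 7)
  expect_length(same, 5)
  for (s in same) expect_equal(s, p)
  # determinism
  e1 <- perturb_ensemble(p, 20, 0.1, seed = 7)
  e2 <- perturb_ensemble(p, 20, 0.1, seed = 7)
  expect_identical(e1, e2)
  expect_false(identical(e1, perturb_ensemble(p, 20, 0.1, seed = 8)))
  # law of large numbers: sample mean within 3 standard errors of the base
  n <- 400
  ens <- perturb_ensemble(list(E = 2e6), n, 0.1, seed = 11)
  vals <- vapply(ens, function(x) x$E, numeric(1))
  se <- 0.1 * 2e6 / sqrt(n)
  expect_lt(abs(mean(vals) - 2e6), 3 * se)
  # non-numeric entries pass through untouched
  expect_identical(e1[[1]]$label, "bm")
  expect_error(perturb_ensemble(p, 5, -0.1, seed = 1), "rel_sd")
})

test_that("configuration resolves defaults, file values and overrides in order", {
  cfg <- cochlea_config()
  expect_s3_class(cfg, "cochlea_config")
  expect_equal(cfg$geometry$a_ow, 5.1e-6)
  expect_equal(cfg$stimulus$ec_gain_db, 26)
  over <- cochlea_config(overrides = list(sal = list(E = 2e5),
                                          scenario = "rwm_x100"))
  expect_equal(over$sal$E, 2e5)
  expect_equal(over$sal$nu, 0.49)          # untouched sibling key survives
  expect_equal(over$scenario, "rwm_x100")
  expect_error(cochlea_config(overrides = list(scenario = "nope")), "scenario")

  # round trip through the resolved-config file
  path <- withr::local_tempfile(fileext = ".yaml")
  write_resolved_config(over, path)
  back <- cochlea_config(file = path)
  expect_equal(back$sal$E, 2e5)
  expect_equal(back$geometry$n_segments, over$geometry$n_segments)
  expect_equal(back$scenario, "rwm_x100")
})
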