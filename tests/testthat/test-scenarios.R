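test_that("configuration paths can be read, overridden and reverted", {
  cfg <- coronary_config("tree.xi" = 2.5, "wall.k3" = 1e6)
  expect_equal(config_get(cfg, "tree.xi"), 2.5)
  expect_equal(config_get(cfg, "wall.k3"), 1e6)
  expect_error(config_set(cfg, "tree.nope", 1), "unknown config path")

  ref <- reference_config(cfg)
  expect_equal(config_get(ref, "tree.xi"), 2.76)
  expect_equal(config_get(ref, "wall.k3"), 8.65e5)
  # solver and heart settings are not reverted
  cfg2 <- coronary_config("solver.n_kernel" = 512)
  expect_equal(config_get(reference_config(cfg2), "solver.n_kernel"), 512)
})

test_that("geometric scaling acts on lengths and radii as configured", {
  tree <- load_vessel_table(coronary_table1())
  sc <- corowave:::scale_tree(tree, 0.9)
  expect_equal(sc$segments$length, 0.9 * tree$segments$length)
  expect_equal(sc$segments$r_dist, 0.9 * tree$segments$r_dist)

  lcx <- corowave:::scale_tree(tree, 0.9, lcx_only = TRUE)
  expect_equal(lcx$segments$length[lcx$segments$name == "RCA"],
               tree$segments$length[tree$segments$name == "RCA"])
  expect_equal(lcx$segments$length[lcx$segments$name == "LCX2"],
               0.9 * tree$segments$length[tree$segments$name == "LCX2"])
})

test_that("scenarios embed their resolved configuration", {
  b <- case_B_scenario()
  expect_equal(config_get(b$config, "tree.xi"), 2.4)
  expect_true(config_get(b$config, "tree.derive_from_xi"))
  expect_s3_class(b$run, "coro_run")
  expect_identical(b$run$config, b$config)
})

test_that("the identity scale reproduces the baseline exactly", {
  base <- baseline_scenario()
  same <- suppressWarnings(
    run_scenario(coarse_cfg(), overrides = list("geometry.scale" = 1.0),
                 name = "identity", probe = "LCX"))
  expect_equal(same$metrics$p_peak, base$metrics$p_peak, tolerance = 1e-12)
  expect_equal(same$metrics$u_peak, base$metrics$u_peak, tolerance = 1e-12)
  expect_equal(100 * same$metrics$u_peak / base$metrics$u_peak, 100)
})
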