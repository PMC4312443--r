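test_that("variants set the inhibition-constant sentinels correctly", {
  p <- default_parameters()
  expect_error(build_variant("nope", p), "unknown variant")
  can <- build_variant("canonical", p)
  expect_identical(can$params$Ki_GEF_GDI, Inf)
  expect_identical(can$params$Ki_GAP_GDI, Inf)
  int <- build_variant("gdi_integrated", p)
  expect_identical(int$params$Ki_GEF_GDI, p$Ki_GEF_GDI)
  expect_identical(int$params$Ki_GAP_GDI, p$Ki_GAP_GDI)
  ng <- build_variant("no_gdi_gef", p)
  expect_identical(ng$params$Ki_GEF_GDI, Inf)
  expect_identical(ng$params$Ki_GAP_GDI, p$Ki_GAP_GDI)
  np <- build_variant("no_gdi_gap", p)
  expect_identical(np$params$Ki_GEF_GDI, p$Ki_GEF_GDI)
  expect_identical(np$params$Ki_GAP_GDI, Inf)
  # topology is identical across variants
  for (v in variant_ids()) {
    expect_identical(build_variant(v, p)$stoich, can$stoich)
  }
})

test_that("inhibition factors at the resting free-GDI level", {
  p <- default_parameters()  # free GDI 0.7 uM, both Ki 0.1 uM
  st <- initial_state(build_variant("gdi_integrated", p))
  expect_equal(noncompetitive_factor(st[["GDI"]], p$Ki_GEF_GDI), 0.125,
               tolerance = 1e-6)
  # canonical: factors identically 1 at any state
  can <- build_variant("canonical", p)
  for (r in can$reactions[4:5]) {
    expect_identical(noncompetitive_factor(2.4, r$law$inhibition$Ki), 1)
  }
  # no_gdi_gap: GAP factor 1, GEF factor < 1 whenever free GDI > 0
  np <- build_variant("no_gdi_gap", p)
  expect_identical(noncompetitive_factor(0.7, np$reactions[[5]]$law$inhibition$Ki), 1)
  expect_lt(noncompetitive_factor(0.7, np$reactions[[4]]$law$inhibition$Ki), 1)
})

test_that("canonical and infinite-Ki gdi_integrated trajectories coincide", {
  p <- default_parameters()
  can <- build_variant("canonical", p)
  int_inf <- build_variant("gdi_integrated",
                           set_parameters(p, Ki_GEF_GDI = Inf,
                                          Ki_GAP_GDI = Inf))
  init <- initial_state(can)
  t1 <- simulate_trajectory(can, 600, 301, init = init)
  t2 <- simulate_trajectory(int_inf, 600, 301, init = init)
  expect_lt(max(abs(t1$states - t2$states)), 1e-9)
  # symmetric removal: knocking one Ki out of gdi_integrated reproduces the
  # corresponding single-removal variant
  ng <- simulate_trajectory(build_variant("no_gdi_gef", p), 600, 301)
  int_ng <- simulate_trajectory(
    build_variant("gdi_integrated", set_parameters(p, Ki_GEF_GDI = Inf)),
    600, 301)
  expect_lt(max(abs(ng$states - int_ng$states)), 1e-9)
  np <- simulate_trajectory(build_variant("no_gdi_gap", p), 600, 301)
  int_np <- simulate_trajectory(
    build_variant("gdi_integrated", set_parameters(p, Ki_GAP_GDI = Inf)),
    600, 301)
  expect_lt(max(abs(np$states - int_np$states)), 1e-9)
})

test_that("initial state is the resting state plus the stimulus impulse", {
  net <- build_variant("gdi_integrated")
  p <- net$params
  s0 <- initial_state(net)
  expect_identical(s0[["Stimulus"]], p$Stimulus_0)
  # GDI/GDP-Rho complex dominates the Rho pool before stimulation
  expect_gt(s0[["GDI_RhoGDP"]], 0.9 * p$Rho_total)
  # free GDI equals the configured excess
  expect_equal(s0[["GDI"]], p$GDI_free_excess, tolerance = 0.01)
  # without a stimulus the system sits at a fixed point: flat trajectory
  p0 <- set_parameters(p, Stimulus_0 = 0)
  net0 <- build_variant("gdi_integrated", p0)
  tr <- simulate_trajectory(net0, 600, 121)
  act <- activation_series(tr)
  expect_lt(max(abs(act - act[1])), 1e-8)
  expect_lt(max(abs(sweep(tr$states, 2, tr$states[1, ]))), 1e-7)
})

test_that("total GDI follows the free-excess parameterisation", {
  p <- default_parameters()
  # closed form at the resting state: g + Rho_total * g / (Kd1 + g)
  g <- p$GDI_free_excess
  Kd1 <- p$koff_re1 / p$kon_re1
  expect_equal(gdi_total_for_free_excess(p),
               g + p$Rho_total * g / (Kd1 + g))
  expect_identical(gdi_total_for_free_excess(
    set_parameters(p, GDI_free_excess = 0)), 0)
  # realised free GDI tracks the target across the scan domain
  for (g in c(0.3, 1.2, 2.4)) {
    net <- build_variant("gdi_integrated",
                         set_parameters(p, GDI_free_excess = g))
    expect_equal(initial_state(net)[["GDI"]], g, tolerance = 0.01 * g)
  }
})
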