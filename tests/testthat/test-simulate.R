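test_that("simulation returns a well-formed trajectory", {
  net <- build_variant("gdi_integrated")
  tr <- simulate_trajectory(net, 600, 301)
  expect_s3_class(tr, "rho_trajectory")
  expect_identical(tr$times, seq(0, 600, length.out = 301))
  expect_true(all(diff(tr$times) > 0))
  expect_identical(colnames(tr$states), rho_species())
  expect_true(tr$solver_info$success)
  expect_true(all(tr$states >= 0))
  expect_error(simulate_trajectory(net, -5), "t_end")
  expect_error(simulate_trajectory(net, 600, 1), "n_points")
})

test_that("conserved totals hold along long stiff trajectories", {
  p <- set_parameters(default_parameters(), Ki_GAP_GDI = 0.01)
  net <- build_variant("gdi_integrated", p)
  tr <- simulate_trajectory(net, 12000, 601)
  tot0 <- conserved_totals(tr$states[1, ])
  drift <- apply(tr$states, 1, function(s) {
    max(abs(conserved_totals(s) - tot0))
  })
  expect_lt(max(drift), 1e-6)
})

test_that("steady state is a fixed point and preserves totals", {
  net <- build_variant("gdi_integrated")
  ss <- steady_state(net)
  rhs <- assemble_rhs(net)
  expect_lt(max(abs(rhs(0, ss, NULL)[[1]])), 1e-10)
  # idempotent
  ss2 <- steady_state(net, seed = ss)
  expect_equal(ss2, ss, tolerance = 1e-9)
  seed <- initial_state(net, add_stimulus = FALSE)
  expect_equal(conserved_totals(steady_state(net, seed)),
               conserved_totals(seed), tolerance = 1e-8)
  # resting activation is negligible relative to the Rho pool
  can <- build_variant("canonical")
  expect_lt(steady_state(can)[["RhoGTP_Effector"]],
            0.01 * can$params$Rho_total)
  # a stimulated state is rejected
  st <- initial_state(net)
  expect_error(steady_state(net, st), "stimulus-free")
})

test_that("results are robust to tolerance and grid refinement", {
  net <- build_variant("gdi_integrated")
  init <- initial_state(net)
  a <- activation_series(simulate_trajectory(net, 600, 301, init = init))
  b <- activation_series(simulate_trajectory(net, 600, 301, init = init,
                                             rtol = 5e-9, atol = 5e-11))
  expect_lt(max(abs(a - b) / max(a)), 0.001)
  s1 <- summarize_activation(simulate_trajectory(net, 600, 601, init = init))
  s2 <- summarize_activation(simulate_trajectory(net, 600, 1201, init = init))
  expect_lt(abs(s1$peak - s2$peak) / s2$peak, 0.005)
  can <- build_variant("canonical")
  init_c <- initial_state(can)
  h1 <- summarize_activation(simulate_trajectory(can, 600, 601,
                                                 init = init_c))
  h2 <- summarize_activation(simulate_trajectory(can, 600, 1201,
                                                 init = init_c))
  expect_lt(abs(h1$half_decay_time - h2$half_decay_time) / h2$half_decay_time,
            0.005)
})

test_that("trajectory CSV export is deterministic and complete", {
  net <- build_variant("canonical")
  init <- initial_state(net)
  tr <- simulate_trajectory(net, 60, 61, init = init)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f1)
  write_trajectory_csv(simulate_trajectory(net, 60, 61, init = init), f2)
  expect_identical(readLines(f1), readLines(f2))
  df <- utils::read.csv(f1)
  expect_identical(names(df), c("time_min", paste0(rho_species(), "_uM")))
  expect_equal(nrow(df), 61)
})
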