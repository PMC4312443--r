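test_that("network structure matches the reaction scheme", {
  net <- rho_network(default_parameters())
  expect_length(net$species, 11)
  expect_false(anyDuplicated(net$species) > 0)
  expect_identical(net$readout, "RhoGTP_Effector")
  expect_identical(vapply(net$reactions, `[[`, "", "id"),
                   paste0("re", 1:8))
  kinds <- vapply(net$reactions, function(r) r$law$kind, "")
  expect_identical(kinds[c(1, 2, 3)], rep("mass_action_reversible", 3))
  expect_identical(kinds[c(4, 5)], rep("michaelis_menten", 2))
  expect_identical(kinds[c(6, 7, 8)], rep("mass_action_irreversible", 3))
  # every species referenced by a reaction is declared
  refs <- unique(unlist(lapply(net$reactions, function(r) {
    c(names(r$reactants), names(r$products), r$enzyme)
  })))
  expect_true(all(refs %in% net$species))
  # inhibition only on the Michaelis-Menten laws
  has_inh <- vapply(net$reactions,
                    function(r) !is.null(r$law$inhibition), logical(1))
  expect_identical(which(has_inh), c(4L, 5L))
})

test_that("RHS vanishes at the zero state and conserves the five pools", {
  net <- rho_network(default_parameters())
  rhs <- assemble_rhs(net)
  zero <- stats::setNames(numeric(11), rho_species())
  expect_identical(rhs(0, zero, NULL)[[1]], numeric(11))
  # stoichiometric conservation at arbitrary states: the derivative of each
  # conserved pool is exactly zero
  pools <- list(
    Rho = c("RhoGDP", "RhoGTP", "GDI_RhoGDP", "GDI_RhoGTP", "RhoGTP_Effector"),
    GDI = c("GDI", "GDI_RhoGDP", "GDI_RhoGTP"),
    GEF = c("GEF_inactive", "GEF_active"),
    GAP = "GAP",
    Effector = c("Effector", "RhoGTP_Effector"))
  for (st in random_states(10, seed = 7)) {
    dy <- stats::setNames(rhs(0, st, NULL)[[1]], rho_species())
    for (p in pools) expect_equal(sum(dy[p]), 0)
  }
})

test_that("effector-binding stoichiometry matches the hand-summed RHS", {
  p <- set_parameters(default_parameters(), kon_re3 = 1, koff_re3 = 0.5)
  net <- rho_network(p)
  st <- stats::setNames(numeric(11), rho_species())
  st["RhoGTP"] <- 1; st["Effector"] <- 1
  # no GDI, GAP, GEF or stimulus present: only re3 fires
  dy <- stats::setNames(assemble_rhs(net)(0, st, NULL)[[1]], rho_species())
  expect_equal(dy[["RhoGTP_Effector"]], 1.0)
  expect_equal(dy[["RhoGTP"]], -1.0)
  expect_equal(dy[["Effector"]], -1.0)
  expect_equal(sum(abs(dy[setdiff(rho_species(),
                                  c("RhoGTP", "Effector",
                                    "RhoGTP_Effector"))])), 0)
})

test_that("conserved totals count each complex once in each pool", {
  zero <- stats::setNames(numeric(11), rho_species())
  expect_identical(unname(conserved_totals(zero)), numeric(5))
  st <- zero; st["GDI_RhoGTP"] <- 0.4
  tot <- conserved_totals(st)
  expect_equal(tot[["Rho_total"]], 0.4)
  expect_equal(tot[["GDI_total"]], 0.4)
  # default initial state reproduces the configured pools
  net <- build_variant("gdi_integrated")
  tot0 <- conserved_totals(initial_state(net))
  p <- net$params
  expect_equal(tot0[["Rho_total"]], p$Rho_total, tolerance = 1e-9)
  expect_equal(tot0[["GEF_total"]], p$GEF_total, tolerance = 1e-9)
  expect_equal(tot0[["GAP_total"]], p$GAP_total, tolerance = 1e-9)
  expect_equal(tot0[["Effector_total"]], p$Effector_total, tolerance = 1e-9)
  expect_equal(tot0[["GDI_total"]], gdi_total_for_free_excess(p),
               tolerance = 1e-6)
})

test_that("infinite-Ki RHS equals the canonical RHS at every state", {
  p <- default_parameters()
  can <- build_variant("canonical", p)
  int_inf <- build_variant("gdi_integrated",
                           set_parameters(p, Ki_GEF_GDI = Inf,
                                          Ki_GAP_GDI = Inf))
  rhs_can <- assemble_rhs(can)
  rhs_int <- assemble_rhs(int_inf)
  for (st in random_states(10, seed = 11)) {
    expect_identical(rhs_can(0, st, NULL)[[1]], rhs_int(0, st, NULL)[[1]])
  }
})

test_that("adaptive trajectories agree with a fixed-step RK4 oracle", {
  net <- build_variant("gdi_integrated")
  init <- initial_state(net)
  t_out <- 0:10
  traj <- simulate_trajectory(net, t_end = 10, n_points = 11, init = init)
  oracle <- rk4_integrate(assemble_rhs(net), init, t_end = 10, dt = 1e-3,
                          t_out = t_out)
  expect_lt(max(abs(traj$states - oracle)), 1e-5)
})
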