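#' Species of the Rho GTPase cycle model
#'
#' The eleven species of the closed reaction scheme, in the canonical
#' order used by every state vector, trajectory column and SBML export:
#' free GDP- and GTP-bound Rho, free GDI, the two GDI/Rho complexes,
#' inactive and active GEF, GAP, free effector, the GTP-Rho/effector
#' complex (the activation readout) and the stimulus.
#'
#' @return Character vector of length 11.
#' @export
rho_species <- function() {
  c("RhoGDP", "RhoGTP", "GDI", "GDI_RhoGDP", "GDI_RhoGTP",
    "GEF_inactive", "GEF_active", "GAP", "Effector", "RhoGTP_Effector",
    "Stimulus")
}

#' Reaction scheme of the Rho GTPase cycle
#'
#' Builds the eight reactions of the cycle as a list of reaction records.
#' re1-re3 are reversible mass-action binding steps (GDI sequestration of
#' GDP-Rho and GTP-Rho, effector binding of GTP-Rho); re4/re5 are the
#' enzymatic Michaelis-Menten steps (GEF-catalysed exchange, GAP-stimulated
#' hydrolysis), each carrying an optional non-competitive inhibition term
#' with free GDI as the inhibitor; re6-re8 form the transient stimulus
#' module (stimulus-driven GEF activation, first-order GEF deactivation,
#' first-order stimulus decay).
#'
#' @param params A parameter set from [default_parameters()]; supplies every
#'   rate constant, the two inhibition constants (possibly `Inf`), and is
#'   validated first.
#' @param inhibitor `"free"` (default) uses the free GDI concentration in
#'   the inhibition factors, `"total"` uses total GDI (free plus
#'   GTPase-complexed); the latter exists for sensitivity analysis only.
#' @return Object of class `rho_network`: list with `species`, `reactions`,
#'   `readout` (fixed to `"RhoGTP_Effector"`), `stoich` (11 x 8 stoichiometry
#'   matrix) and `inhibitor`.
#' @export
rho_network <- function(params = default_parameters(),
                        inhibitor = c("free", "total")) {
  params <- validate_parameters(params)
  inhibitor <- match.arg(inhibitor)
  rx <- function(id, reactants, products, kind, constants,
                 enzyme = NULL, inhibition = NULL) {
    list(id = id, reactants = reactants, products = products,
         enzyme = enzyme,
         law = list(kind = kind, constants = constants,
                    inhibition = inhibition))
  }
  reactions <- list(
    rx("re1", c(GDI = 1, RhoGDP = 1), c(GDI_RhoGDP = 1),
       "mass_action_reversible",
       c(kon = params$kon_re1, koff = params$koff_re1)),
    rx("re2", c(GDI = 1, RhoGTP = 1), c(GDI_RhoGTP = 1),
       "mass_action_reversible",
       c(kon = params$kon_re2, koff = params$koff_re2)),
    rx("re3", c(RhoGTP = 1, Effector = 1), c(RhoGTP_Effector = 1),
       "mass_action_reversible",
       c(kon = params$kon_re3, koff = params$koff_re3)),
    rx("re4", c(RhoGDP = 1), c(RhoGTP = 1), "michaelis_menten",
       c(kcat = params$kcat_GEF, Km = params$Km_GEF),
       enzyme = "GEF_active",
       inhibition = list(inhibitor_species = "GDI", Ki = params$Ki_GEF_GDI)),
    rx("re5", c(RhoGTP = 1), c(RhoGDP = 1), "michaelis_menten",
       c(kcat = params$kcat_GAP, Km = params$Km_GAP),
       enzyme = "GAP",
       inhibition = list(inhibitor_species = "GDI", Ki = params$Ki_GAP_GDI)),
    rx("re6", c(Stimulus = 1, GEF_inactive = 1), c(GEF_active = 1),
       "mass_action_irreversible", c(kon = params$k_stim_act)),
    rx("re7", c(GEF_active = 1), c(GEF_inactive = 1),
       "mass_action_irreversible", c(kon = params$k_gef_deact)),
    rx("re8", c(Stimulus = 1), stats::setNames(numeric(0), character(0)),
       "mass_action_irreversible", c(kon = params$k_stim_decay))
  )
  species <- rho_species()
  stoich <- matrix(0, nrow = length(species), ncol = length(reactions),
                   dimnames = list(species, vapply(reactions, `[[`, "", "id")))
  for (r in reactions) {
    stoich[names(r$reactants), r$id] <-
      stoich[names(r$reactants), r$id] - r$reactants
    if (length(r$products)) {
      stoich[names(r$products), r$id] <-
        stoich[names(r$products), r$id] + r$products
    }
  }
  structure(list(species = species, reactions = reactions,
                 readout = "RhoGTP_Effector", stoich = stoich,
                 inhibitor = inhibitor, params = params),
            class = "rho_network")
}

#' @export
print.rho_network <- function(x, ...) {
  cat("Rho GTPase cycle network: ", length(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  cat("  readout:", x$readout, "\n")
  cat("  Ki_GEF_GDI:", x$params$Ki_GEF_GDI,
      " Ki_GAP_GDI:", x$params$Ki_GAP_GDI, "(uM; Inf = no interaction)\n")
  invisible(x)
}

#' Reaction flux vector at a state
#'
#' Evaluates all eight reaction fluxes (uM/min) at a concentration vector.
#' For re4/re5 the non-competitive factor is evaluated on the current
#' free-GDI concentration (or total GDI if the network was built with
#' `inhibitor = "total"`).
#'
#' @param network A [rho_network()].
#' @param state Named numeric vector over the 11 species, uM.
#' @return Named numeric vector of 8 fluxes.
#' @export
reaction_fluxes <- function(network, state) {
  gdi_inhibitor <- if (network$inhibitor == "free") {
    state[["GDI"]]
  } else {
    state[["GDI"]] + state[["GDI_RhoGDP"]] + state[["GDI_RhoGTP"]]
  }
  # clamp transient solver undershoot so the inhibition factor stays defined
  gdi_inhibitor <- max(gdi_inhibitor, 0)
  v <- vapply(network$reactions, function(r) {
    if (r$law$kind == "michaelis_menten") {
      S <- max(state[[names(r$reactants)]], 0)
      E <- max(state[[r$enzyme]], 0)
      f <- noncompetitive_factor(gdi_inhibitor, r$law$inhibition$Ki)
      mm_velocity(r$law$constants[["kcat"]], E, S, r$law$constants[["Km"]], f)
    } else {
      mass_action_flux(r, state)
    }
  }, numeric(1))
  stats::setNames(v, vapply(network$reactions, `[[`, "", "id"))
}

#' Assemble the ODE right-hand side of a network
#'
#' Returns a derivative function in the form deSolve expects:
#' `function(t, y, parms)` returning `list(dy)`, with
#' `dy = stoichiometry %*% fluxes`. The system is autonomous; stimulation
#' enters through the initial condition.
#'
#' @param network A [rho_network()].
#' @return Function `(t, y, parms) -> list(dy)` over the 11 species.
#' @export
assemble_rhs <- function(network) {
  stoich <- network$stoich
  force(network)
  function(t, y, parms) {
    list(as.vector(stoich %*% reaction_fluxes(network, y)))
  }
}

#' Conserved molecular totals of a state
#'
#' The closed reaction scheme conserves five pools: total Rho (free GDP- and
#' GTP-bound forms plus all complexes), total GDI, total GEF, total GAP and
#' total effector. The stimulus is the only non-conserved species (it decays
#' and is consumed by GEF activation). These totals are the package's main
#' numerical-integrity check: they must stay constant along any trajectory.
#'
#' @param state Named numeric vector over the 11 species, uM.
#' @return Named numeric vector with `Rho_total`, `GDI_total`, `GEF_total`,
#'   `GAP_total`, `Effector_total` (uM).
#' @export
conserved_totals <- function(state) {
  c(Rho_total = unname(state[["RhoGDP"]] + state[["RhoGTP"]] +
                         state[["GDI_RhoGDP"]] + state[["GDI_RhoGTP"]] +
                         state[["RhoGTP_Effector"]]),
    GDI_total = unname(state[["GDI"]] + state[["GDI_RhoGDP"]] +
                         state[["GDI_RhoGTP"]]),
    GEF_total = unname(state[["GEF_inactive"]] + state[["GEF_active"]]),
    GAP_total = unname(state[["GAP"]]),
    Effector_total = unname(state[["Effector"]] + state[["RhoGTP_Effector"]]))
}
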