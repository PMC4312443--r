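#' Non-competitive inhibition factor
#'
#' Classical single-site non-competitive inhibition scales the maximal
#' velocity of a Michaelis-Menten enzyme by `1 / (1 + I / Ki)`, where `I`
#' is the inhibitor concentration. The inhibitor binds the free enzyme and
#' the enzyme-substrate complex with equal affinity, so the factor is
#' independent of the substrate concentration. Here the inhibitor is free
#' (non-GTPase-complexed) RhoGDI acting on GEF or GAP catalysis.
#'
#' `Ki = Inf` is the sentinel for "no interaction": the factor is exactly 1
#' and the law collapses to plain Michaelis-Menten kinetics. This is how
#' model variants remove a GDI/GEF or GDI/GAP interaction without changing
#' the network topology.
#'
#' @param inhibitor_conc Inhibitor (free GDI) concentration, uM. Must be
#'   non-negative.
#' @param Ki Inhibition constant, uM. Strictly positive; may be `Inf` to
#'   disable inhibition.
#' @return Dimensionless factor in (0, 1].
#' @examples
#' noncompetitive_factor(0, 0.1)    # 1: no inhibitor
#' noncompetitive_factor(0.1, 0.1)  # 0.5: half-inhibition at I = Ki
#' noncompetitive_factor(0.7, Inf)  # 1: interaction disabled
#' @export
noncompetitive_factor <- function(inhibitor_conc, Ki) {
  if (any(!is.finite(inhibitor_conc)) || any(inhibitor_conc < 0)) {
    stop("invalid parameter: inhibitor concentration must be finite and >= 0",
         call. = FALSE)
  }
  if (any(is.na(Ki)) || any(Ki <= 0)) {
    stop("invalid parameter: Ki must be > 0 (Inf disables inhibition)",
         call. = FALSE)
  }
  ifelse(is.infinite(Ki), 1, 1 / (1 + inhibitor_conc / Ki))
}

#' Michaelis-Menten velocity with optional inhibition factor
#'
#' `v = kcat * E * S / (Km + S) * factor`. Used for the GEF-catalysed
#' nucleotide exchange (GDP-Rho -> GTP-Rho) and the GAP-stimulated
#' hydrolysis (GTP-Rho -> GDP-Rho), with `factor` supplied by
#' [noncompetitive_factor()].
#'
#' @param kcat Turnover number, 1/min.
#' @param enzyme_conc Enzyme concentration, uM.
#' @param substrate_conc Substrate concentration, uM.
#' @param Km Michaelis constant, uM. Strictly positive.
#' @param inhibition_factor Dimensionless scaling in (0, 1]; default 1.
#' @return Reaction velocity, uM/min.
#' @export
mm_velocity <- function(kcat, enzyme_conc, substrate_conc, Km,
                        inhibition_factor = 1) {
  if (any(is.na(Km)) || any(Km <= 0)) {
    stop("invalid parameter: Km must be > 0", call. = FALSE)
  }
  if (any(kcat < 0) || any(enzyme_conc < 0) || any(substrate_conc < 0)) {
    stop("invalid parameter: kcat, enzyme and substrate must be >= 0",
         call. = FALSE)
  }
  kcat * enzyme_conc * substrate_conc / (Km + substrate_conc) *
    inhibition_factor
}

#' Net mass-action flux of a single reaction
#'
#' Reversible laws: `kon * prod(reactants) - koff * prod(products)`;
#' irreversible laws: `kon * prod(reactants)`. Reactions are at most
#' bimolecular here, so `prod` is a product of one or two concentrations.
#'
#' @param reaction A reaction entry from [rho_network()], with
#'   `law$kind` one of `"mass_action_reversible"`,
#'   `"mass_action_irreversible"`.
#' @param state Named numeric vector of concentrations (uM) covering every
#'   species the reaction references.
#' @return Net flux, uM/min (positive in the forward direction).
#' @export
mass_action_flux <- function(reaction, state) {
  law <- reaction$law
  if (!law$kind %in% c("mass_action_reversible", "mass_action_irreversible")) {
    stop("mass_action_flux: reaction '", reaction$id,
         "' does not use a mass-action law", call. = FALSE)
  }
  kon <- law$constants[["kon"]]
  if (is.null(kon) || is.na(kon)) {
    stop("configuration error: missing 'kon' for reaction ", reaction$id,
         call. = FALSE)
  }
  fwd <- kon * prod(state[names(reaction$reactants)]^reaction$reactants)
  if (law$kind == "mass_action_irreversible") {
    return(unname(fwd))
  }
  koff <- law$constants[["koff"]]
  if (is.null(koff) || is.na(koff)) {
    stop("configuration error: missing 'koff' for reaction ", reaction$id,
         call. = FALSE)
  }
  unname(fwd - koff * prod(state[names(reaction$products)]^reaction$products))
}
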