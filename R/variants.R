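#' Model variant identifiers
#'
#' The four variants of the Rho GTPase cycle model:
#' \describe{
#'   \item{canonical}{GDI regulates only by sequestering the GTPase; both
#'     inhibition constants are the `Inf` sentinel, so GEF and GAP catalysis
#'     is uninhibited.}
#'   \item{gdi_integrated}{GDI additionally inhibits GEF and GAP catalysis
#'     non-competitively; both inhibition constants finite.}
#'   \item{no_gdi_gef}{GDI/GEF interaction removed from the GDI-integrated
#'     model (`Ki_GEF_GDI = Inf`); GDI/GAP interaction retained.}
#'   \item{no_gdi_gap}{GDI/GAP interaction removed (`Ki_GAP_GDI = Inf`);
#'     GDI/GEF interaction retained.}
#' }
#'
#' @return Character vector of the four variant names.
#' @export
variant_ids <- function() {
  c("canonical", "gdi_integrated", "no_gdi_gef", "no_gdi_gap")
}

#' Build a model variant
#'
#' All four variants share an identical network topology; removing a
#' GDI/GEF or GDI/GAP interaction is implemented by setting the
#' corresponding inhibition constant to the `Inf` sentinel (inhibition
#' factor identically 1), never by deleting a reaction. `gdi_integrated`
#' uses the inhibition constants exactly as supplied in `params`, so
#' setting them to `Inf` there reproduces the canonical model — a
#' consistency property the test suite exercises.
#'
#' @param variant One of [variant_ids()].
#' @param params Baseline parameter set; default [default_parameters()].
#' @param inhibitor Passed to [rho_network()]: `"free"` (default) or
#'   `"total"` GDI as the inhibiting species.
#' @return A [rho_network()] whose embedded parameter set carries the
#'   variant's effective inhibition constants.
#' @export
build_variant <- function(variant, params = default_parameters(),
                          inhibitor = c("free", "total")) {
  if (!is.character(variant) || length(variant) != 1 ||
      !variant %in% variant_ids()) {
    stop("unknown variant: must be one of ",
         paste(variant_ids(), collapse = ", "), call. = FALSE)
  }
  params <- validate_parameters(params)
  eff <- switch(variant,
    canonical      = set_parameters(params, Ki_GEF_GDI = Inf,
                                    Ki_GAP_GDI = Inf),
    gdi_integrated = params,
    no_gdi_gef     = set_parameters(params, Ki_GEF_GDI = Inf),
    no_gdi_gap     = set_parameters(params, Ki_GAP_GDI = Inf))
  net <- rho_network(eff, inhibitor = match.arg(inhibitor))
  net$variant <- variant
  net
}

#' Total GDI for a target free-GDI excess
#'
#' The model is parameterised by the free (non-GTPase-complexed) GDI
#' concentration at the pre-stimulus resting state, not by total GDI. In
#' that resting state no GTP-Rho is present, so only the GDI + GDP-Rho
#' binding equilibrium (dissociation constant `Kd1 = koff_re1/kon_re1`)
#' determines the partition, and the total follows in closed form:
#' with free GDI `g`, sequestered GDI is `Rho_total * g / (Kd1 + g)` and
#' `GDI_total = g + Rho_total * g / (Kd1 + g)`. A target of 0 means no
#' GDI in the system at all.
#'
#' @param params A `rho_params`; `GDI_free_excess` is the target, uM.
#' @return Total GDI, uM.
#' @export
gdi_total_for_free_excess <- function(params) {
  params <- validate_parameters(params)
  g <- params$GDI_free_excess
  Kd1 <- params$koff_re1 / params$kon_re1
  g + params$Rho_total * g / (Kd1 + g)
}

#' Pre-stimulus initial state with stimulus added at t = 0
#'
#' Constructs the resting state of the cycle — the unstimulated system
#' relaxed to steady state, in which the GDI/GDP-Rho complex is the
#' dominant Rho pool and the free-GDI concentration equals the configured
#' excess — then adds the stimulus pool `Stimulus_0` to model stimulation
#' as an impulse at t = 0. The analytic binding equilibrium seeds the
#' relaxation; [steady_state()] then polishes it to
#' `max |d/dt| < 1e-10` uM/min, and the realised free-GDI concentration is
#' verified to be within 1% of the target.
#'
#' @param network A built variant from [build_variant()] (or any
#'   [rho_network()]).
#' @param add_stimulus If `FALSE`, return the resting state itself
#'   (stimulus 0).
#' @return Named concentration vector over the 11 species, uM.
#' @export
initial_state <- function(network, add_stimulus = TRUE) {
  stopifnot(inherits(network, "rho_network"))
  p <- network$params
  g <- p$GDI_free_excess
  Kd1 <- p$koff_re1 / p$kon_re1
  seq_gdi <- p$Rho_total * g / (Kd1 + g)
  seed <- stats::setNames(numeric(length(network$species)), network$species)
  seed["RhoGDP"] <- p$Rho_total - seq_gdi
  seed["GDI_RhoGDP"] <- seq_gdi
  seed["GDI"] <- g
  seed["GEF_inactive"] <- p$GEF_total
  seed["GAP"] <- p$GAP_total
  seed["Effector"] <- p$Effector_total
  rest <- steady_state(network, seed)
  if (g > 0 && abs(rest[["GDI"]] - g) / g > 0.01) {
    stop("numerical error: pre-stimulus free GDI ",
         signif(rest[["GDI"]], 6), " uM deviates > 1% from target ", g,
         " uM", call. = FALSE)
  }
  if (add_stimulus) rest["Stimulus"] <- p$Stimulus_0
  rest
}
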