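# Seeded log-uniform parameter perturbation and robustness analysis.
#
# The baseline kinetic constants are calibrated values rather than measured
# ones, so the qualitative conclusions are checked for robustness by
# re-running the model-comparison experiments on parameter sets drawn
# around the baseline. Constants with a stated provenance (the free-GDI
# excess and the scanned inhibition-constant / regulator-concentration
# values) are never perturbed.

.default_fixed <- c("GDI_free_excess", "Ki_GEF_GDI", "Ki_GAP_GDI",
                    "GEF_total", "GAP_total")

.behavior_names <- c("transient_canonical", "sustained_gdi_integrated",
                     "gap_interaction_necessity", "ki_gap_monotonicity",
                     "free_gdi_effects", "gap_concentration_effect")

#' Perturbation specification
#'
#' @param seed Integer seed; the single source of randomness.
#' @param spread Log10 half-width per constant, decades (default 0.5):
#'   each perturbed constant is drawn log-uniformly from
#'   `[default / 10^spread, default * 10^spread]`.
#' @param fixed Field names held at their baseline values; defaults to the
#'   stated-provenance set (free-GDI excess, inhibition constants, GEF/GAP
#'   pools).
#' @return Object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(seed = 1L, spread = 0.5,
                              fixed = .default_fixed) {
  if (!is.numeric(spread) || length(spread) != 1 || spread < 0) {
    stop("usage error: spread must be a single value >= 0", call. = FALSE)
  }
  bad <- setdiff(fixed, .param_fields)
  if (length(bad)) {
    stop("usage error: unknown fixed field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(seed = as.integer(seed), spread = spread, fixed = fixed),
            class = "perturbation_spec")
}

#' Draw perturbed parameter sets
#'
#' Each non-fixed, strictly-positive constant of the baseline is multiplied
#' by an independent log-uniform factor within `spread` decades. Draws are
#' deterministic under `(seed, n)` and leave the caller's RNG state
#' untouched.
#'
#' @param spec A [perturbation_spec()].
#' @param n Number of sets (>= 1).
#' @param base Baseline parameters; default [default_parameters()].
#' @return List of `n` validated `rho_params` objects.
#' @export
sample_parameters <- function(spec, n, base = default_parameters()) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (n < 1) stop("usage error: n must be >= 1", call. = FALSE)
  base <- validate_parameters(base)
  perturb <- setdiff(.param_fields, spec$fixed)
  # zero pools and Inf sentinels have no meaningful log-scale neighbourhood
  perturb <- perturb[vapply(perturb, function(f) {
    is.finite(base[[f]]) && base[[f]] > 0
  }, logical(1))]
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  lapply(seq_len(n), function(i) {
    fac <- 10^stats::runif(length(perturb), -spec$spread, spec$spread)
    p <- as.list(base)
    p[perturb] <- mapply(`*`, p[perturb], fac, SIMPLIFY = FALSE)
    validate_parameters(p)
  })
}

#' Qualitative behaviours of the model comparison
#'
#' Evaluates, for one parameter set, the six qualitative behaviours that
#' the baseline is calibrated to show:
#' \describe{
#'   \item{transient_canonical}{canonical: activation rises after
#'     stimulation and its 600-min sustained ratio is below 0.5.}
#'   \item{sustained_gdi_integrated}{GDI-integrated sustained ratio exceeds
#'     the canonical one.}
#'   \item{gap_interaction_necessity}{removing the GDI/GAP interaction
#'     lowers the sustained ratio below the GDI-integrated value, while
#'     removing the GDI/GEF interaction leaves the ratio within 20% and
#'     raises the peak.}
#'   \item{ki_gap_monotonicity}{the sustained ratio is nonincreasing in
#'     `Ki_GAP_GDI` across its grid, at every `Ki_GEF_GDI`.}
#'   \item{free_gdi_effects}{peak activation strictly decreases with free
#'     GDI in both models, and GDI-integrated activation at 1800 min with
#'     free GDI > 0 exceeds the value without free GDI.}
#'   \item{gap_concentration_effect}{the sustained ratio strictly decreases
#'     with `GAP_total` across its grid, at every `GEF_total`.}
#' }
#'
#' @param params Parameter set to test.
#' @param ki_values,conc_values,gdi_values Grids used by the monotonicity
#'   checks; defaults are the standard scan grids (the free-GDI grid is
#'   thinned to 5 points to keep the robustness report fast).
#' @return Named logical vector of length 6.
#' @export
check_behaviors <- function(params = default_parameters(),
                            ki_values = c(0.01, 0.1, 1.0),
                            conc_values = c(0.1, 0.3, 0.9),
                            gdi_values = seq(0, 2.4, length.out = 5)) {
  params <- validate_parameters(params)
  fig1 <- fig_variant_timecourses(params)$summaries
  rownames(fig1) <- fig1$variant
  rises <- {
    act <- activation_series(
      fig_variant_timecourses(params, t_end = 600,
                              n_points = 601)$trajectories$canonical)
    max(act) > act[1] + 1e-9
  }
  b1 <- rises && fig1["canonical", "sustained_ratio"] < 0.5
  b2 <- fig1["gdi_integrated", "sustained_ratio"] >
    fig1["canonical", "sustained_ratio"]
  ref <- fig1["gdi_integrated", "sustained_ratio"]
  b3 <- fig1["no_gdi_gap", "sustained_ratio"] < ref &&
    abs(fig1["no_gdi_gef", "sustained_ratio"] - ref) <= 0.2 * ref &&
    fig1["no_gdi_gef", "peak"] > fig1["gdi_integrated", "peak"]
  ki <- scan_ki_and_conc(params, ki_values = ki_values,
                         conc_values = conc_values)
  kig <- ki[ki$scan == "ki_grid", ]
  b4 <- all(vapply(ki_values, function(kge) {
    r <- kig[kig$Ki_GEF_GDI == kge, ]
    r <- r[order(r$Ki_GAP_GDI), ]
    all(diff(r$sustained_ratio) <= 1e-9)
  }, logical(1)))
  gdi <- scan_free_gdi(gdi_values, params, horizons = c(600, 1800))
  peaks_dec <- all(vapply(c("canonical", "gdi_integrated"), function(v) {
    r <- gdi[gdi$variant == v & gdi$horizon_min == 600, ]
    r <- r[order(r$GDI_free_excess), ]
    all(diff(r$peak) < 0)
  }, logical(1)))
  g18 <- gdi[gdi$variant == "gdi_integrated" & gdi$horizon_min == 1800, ]
  g18 <- g18[order(g18$GDI_free_excess), ]
  b5 <- peaks_dec &&
    all(g18$activation_at_horizon[g18$GDI_free_excess > 0] >
          g18$activation_at_horizon[g18$GDI_free_excess == 0])
  cg <- ki[ki$scan == "conc_grid", ]
  b6 <- all(vapply(conc_values, function(gef) {
    r <- cg[cg$GEF_total == gef, ]
    r <- r[order(r$GAP_total), ]
    all(diff(r$sustained_ratio) < 0)
  }, logical(1)))
  c(transient_canonical = b1, sustained_gdi_integrated = b2,
    gap_interaction_necessity = b3, ki_gap_monotonicity = b4,
    free_gdi_effects = b5, gap_concentration_effect = b6)
}

#' Robustness report over perturbed parameter sets
#'
#' Draws `n` perturbed parameter sets and evaluates the six qualitative
#' behaviours on each, reporting per-behaviour pass fractions and per-set
#' diagnostics. With `spread = 0` all fractions are 1 by construction
#' (every draw is the baseline).
#'
#' @param n Number of parameter sets.
#' @param seed Integer seed.
#' @param spread Log10 half-width, decades (default 0.25).
#' @param base Baseline parameters.
#' @param ... Passed to [check_behaviors()] (grid overrides).
#' @return Object of class `robustness_report`: list with `fractions`
#'   (named numeric, length 6), `details` (n x 6 logical data.frame),
#'   `seed`, `spread`, `n`.
#' @export
robustness_report <- function(n, seed = 1L, spread = 0.25,
                              base = default_parameters(), ...) {
  spec <- perturbation_spec(seed = seed, spread = spread)
  sets <- sample_parameters(spec, n, base = base)
  rows <- lapply(seq_along(sets), function(i) {
    # a draw that breaks the integrator simply fails every behaviour
    ok <- tryCatch(check_behaviors(sets[[i]], ...),
                   error = function(e) {
                     stats::setNames(rep(FALSE, 6), .behavior_names)
                   })
    as.data.frame(as.list(ok))
  })
  details <- do.call(rbind, rows)
  structure(list(fractions = colMeans(details), details = details,
                 seed = as.integer(seed), spread = spread, n = n),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Robustness report: n =", x$n, " spread =", x$spread,
      "decades, seed =", x$seed, "\n")
  for (nm in names(x$fractions)) {
    cat(sprintf("  %-28s %.2f\n", nm, x$fractions[[nm]]))
  }
  invisible(x)
}

#' Write a robustness report to CSV
#'
#' One row per behaviour with its pass fraction, preceded by `# seed=` /
#' `# spread=` comment lines recording the draw.
#'
#' @param report A `robustness_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_robustness_csv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed=%d spread=%g n=%d", report$seed,
                       report$spread, report$n),
               "behavior,pass_fraction",
               sprintf("%s,%g", names(report$fractions),
                       report$fractions)), con)
  invisible(path)
}
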