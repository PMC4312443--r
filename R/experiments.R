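# Scan drivers that regenerate the package's standard computational
# experiments: model-variant time courses, free-GDI scans, inhibition-constant
# and regulator-concentration grids, and the Ki x free-GDI grid on long
# horizons. All scans are deterministic (no replicates).

# Simulate one parameterisation to the largest horizon and summarise the
# activation dynamics at each requested horizon. sustained_ratio is always
# evaluated at the 600-min reference so every record shares one definition.
scan_point <- function(variant, params, horizons, inhibitor = "free") {
  t_max <- max(horizons)
  step <- if (t_max <= 2400) 1 else 5
  net <- build_variant(variant, params, inhibitor = inhibitor)
  traj <- simulate_trajectory(net, t_end = t_max,
                              n_points = as.integer(t_max / step) + 1L)
  do.call(rbind, lapply(horizons, function(h) {
    sub <- truncate_trajectory(traj, h)
    s <- summarize_activation(sub, reference_times = c(min(600, h), h))
    data.frame(variant = variant, horizon_min = h,
               activation_at_horizon = unname(s$value_at[as.character(h)]),
               peak = s$peak, time_to_peak = s$time_to_peak,
               half_decay_time = s$half_decay_time, auc = s$auc,
               sustained_ratio = s$sustained_ratio,
               sustained = s$sustained_ratio >= SUSTAINED_RATIO_THRESHOLD,
               stringsAsFactors = FALSE)
  }))
}

# Restrict a trajectory to [0, t_end]; t_end must lie on the grid.
truncate_trajectory <- function(traj, t_end) {
  keep <- traj$times <= t_end + 1e-9
  structure(list(times = traj$times[keep],
                 states = traj$states[keep, , drop = FALSE],
                 network = traj$network, solver_info = traj$solver_info),
            class = "rho_trajectory")
}

#' Time courses of the four model variants
#'
#' Simulates all four variants from the same baseline parameter set and
#' summarises each activation time course. This is the experiment that
#' exposes the package's central result: the canonical model responds to
#' stimulation with a transient pulse of active Rho, whereas the
#' GDI-integrated model sustains activation; removing the GDI/GAP
#' interaction abolishes the sustainment, while removing the GDI/GEF
#' interaction preserves the shape at a roughly two-fold higher level.
#'
#' @param params Baseline parameters; default [default_parameters()].
#' @param t_end Horizon, min (default 600).
#' @param n_points Grid points (default one per minute).
#' @return List with `trajectories` (named list of `rho_trajectory`, one per
#'   variant) and `summaries` (data.frame, one row per variant).
#' @export
fig_variant_timecourses <- function(params = default_parameters(),
                                    t_end = 600, n_points = t_end + 1) {
  trajs <- lapply(variant_ids(), function(v) {
    simulate_trajectory(build_variant(v, params), t_end = t_end,
                        n_points = n_points)
  })
  names(trajs) <- variant_ids()
  summaries <- do.call(rbind, lapply(variant_ids(), function(v) {
    s <- summarize_activation(trajs[[v]],
                              reference_times = c(min(600, t_end), t_end))
    data.frame(variant = v, peak = s$peak, time_to_peak = s$time_to_peak,
               activation_at_end = unname(s$value_at[as.character(t_end)]),
               half_decay_time = s$half_decay_time, auc = s$auc,
               sustained_ratio = s$sustained_ratio,
               sustained = s$sustained_ratio >= SUSTAINED_RATIO_THRESHOLD,
               stringsAsFactors = FALSE)
  }))
  list(trajectories = trajs, summaries = summaries)
}

#' Free-GDI concentration scan
#'
#' Simulates the canonical and GDI-integrated models across a grid of free
#' (non-GTPase-complexed) GDI concentrations. In the canonical model more
#' free GDI only depresses activation; in the GDI-integrated model it also
#' prolongs it, because free GDI inhibits GAP catalysis.
#'
#' @param gdi_values Free-GDI excess grid, uM; default 9 evenly spaced
#'   values on \[0, 2.4\].
#' @param params Baseline parameters.
#' @param variants Variants to scan (default canonical and gdi_integrated).
#' @param horizons Horizons, min (default 600 and 1800).
#' @return Tidy data.frame, one row per (variant, free-GDI value, horizon),
#'   with the activation summary columns of [summarize_activation()].
#' @export
scan_free_gdi <- function(gdi_values = seq(0, 2.4, length.out = 9),
                          params = default_parameters(),
                          variants = c("canonical", "gdi_integrated"),
                          horizons = c(600, 1800)) {
  if (any(gdi_values < 0)) stop("free-GDI values must be >= 0", call. = FALSE)
  out <- do.call(rbind, lapply(variants, function(v) {
    do.call(rbind, lapply(gdi_values, function(g) {
      rec <- scan_point(v, set_parameters(params, GDI_free_excess = g),
                        horizons)
      cbind(data.frame(GDI_free_excess = g), rec)
    }))
  }))
  out[, c("variant", setdiff(names(out), "variant"))]
}

#' Inhibition-constant and regulator-concentration grids
#'
#' Two 3 x 3 grids on the GDI-integrated model at the 600-min horizon:
#' the inhibition constants `Ki_GEF_GDI` x `Ki_GAP_GDI` over
#' \{0.01, 0.1, 1.0\} uM, and the regulator pools `GEF_total` x `GAP_total`
#' over \{0.1, 0.3, 0.9\} uM. Lower `Ki_GAP_GDI` (tighter GDI/GAP
#' interaction) prolongs activation at every `Ki_GEF_GDI`; lower
#' `Ki_GEF_GDI` depresses the overall level; higher GAP concentration
#' negates the sustainment.
#'
#' @param params Baseline parameters.
#' @param ki_values Inhibition-constant grid, uM.
#' @param conc_values GEF/GAP pool grid, uM.
#' @param horizon Horizon, min (default 600).
#' @return Tidy data.frame with a `scan` column (`"ki_grid"` or
#'   `"conc_grid"`), the two grid columns, and the summary columns.
#' @export
scan_ki_and_conc <- function(params = default_parameters(),
                             ki_values = c(0.01, 0.1, 1.0),
                             conc_values = c(0.1, 0.3, 0.9),
                             horizon = 600) {
  ki_grid <- expand.grid(Ki_GEF_GDI = ki_values, Ki_GAP_GDI = ki_values)
  ki <- do.call(rbind, lapply(seq_len(nrow(ki_grid)), function(i) {
    p <- set_parameters(params, Ki_GEF_GDI = ki_grid$Ki_GEF_GDI[i],
                        Ki_GAP_GDI = ki_grid$Ki_GAP_GDI[i])
    cbind(data.frame(scan = "ki_grid", Ki_GEF_GDI = ki_grid$Ki_GEF_GDI[i],
                     Ki_GAP_GDI = ki_grid$Ki_GAP_GDI[i],
                     GEF_total = NA_real_, GAP_total = NA_real_),
          scan_point("gdi_integrated", p, horizon))
  }))
  conc_grid <- expand.grid(GEF_total = conc_values, GAP_total = conc_values)
  conc <- do.call(rbind, lapply(seq_len(nrow(conc_grid)), function(i) {
    p <- set_parameters(params, GEF_total = conc_grid$GEF_total[i],
                        GAP_total = conc_grid$GAP_total[i])
    cbind(data.frame(scan = "conc_grid", Ki_GEF_GDI = NA_real_,
                     Ki_GAP_GDI = NA_real_,
                     GEF_total = conc_grid$GEF_total[i],
                     GAP_total = conc_grid$GAP_total[i]),
          scan_point("gdi_integrated", p, horizon))
  }))
  rbind(ki, conc)
}

#' GDI/GAP inhibition constant x free-GDI grid on long horizons
#'
#' The GDI-integrated model across `Ki_GAP_GDI` in \{0.01, 0.1, 1.0\} uM and
#' free-GDI excess on \[0, 2.4\] uM, summarised at 600 and 12,000 min. At
#' the tightest GDI/GAP interaction and sufficient free GDI the activation
#' half-decay time exceeds the 12,000-min horizon — the extremely
#' long-term retention of the activated state.
#'
#' @param ki_values `Ki_GAP_GDI` grid, uM.
#' @param gdi_values Free-GDI excess grid, uM.
#' @param params Baseline parameters.
#' @param horizons Horizons, min (default 600 and 12,000).
#' @return Tidy data.frame, one row per (Ki, free GDI, horizon).
#' @export
scan_ki_gap_by_free_gdi <- function(ki_values = c(0.01, 0.1, 1.0),
                                    gdi_values = seq(0, 2.4, length.out = 9),
                                    params = default_parameters(),
                                    horizons = c(600, 12000)) {
  grid <- expand.grid(Ki_GAP_GDI = ki_values, GDI_free_excess = gdi_values)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    p <- set_parameters(params, Ki_GAP_GDI = grid$Ki_GAP_GDI[i],
                        GDI_free_excess = grid$GDI_free_excess[i])
    cbind(data.frame(Ki_GAP_GDI = grid$Ki_GAP_GDI[i],
                     GDI_free_excess = grid$GDI_free_excess[i]),
          scan_point("gdi_integrated", p, horizons))
  }))
}

#' Write a scan result to CSV
#'
#' @param scan A data.frame from one of the scan drivers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  utils::write.csv(scan, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot activation time courses
#'
#' Base-graphics line chart of the activation readout for one or more
#' trajectories.
#'
#' @param trajs A `rho_trajectory` or a (optionally named) list of them.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of plotted series.
#' @export
plot_activation <- function(trajs, ...) {
  if (inherits(trajs, "rho_trajectory")) trajs <- list(trajs)
  times <- trajs[[1]]$times
  y <- vapply(trajs, activation_series, numeric(length(times)))
  graphics::matplot(times, y, type = "l", lty = 1,
                    xlab = "time after stimulation (min)",
                    ylab = "[GTP-Rho/Effector] (uM)", ...)
  if (!is.null(names(trajs))) {
    graphics::legend("topright", legend = names(trajs),
                     col = seq_along(trajs), lty = 1, bty = "n")
  }
  invisible(y)
}
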