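#' Simulate a model variant over a time horizon
#'
#' Integrates the ODE system with a stiff-capable adaptive solver
#' (deSolve's `lsoda`) and returns the trajectory on a uniform grid.
#' The long scan horizons (up to 12,000 min) combined with fast binding
#' reactions make the system moderately stiff, hence the tight default
#' tolerances. After integration the five conserved totals are checked
#' against their initial values; a breach beyond `cons_tol` aborts.
#' Concentrations more negative than -1e-8 uM abort as a
#' numerical-integrity failure; smaller undershoots are clipped to 0 in
#' the reported states.
#'
#' @param network A built variant from [build_variant()].
#' @param t_end Horizon, min (> 0). Time 0 is the moment of stimulation.
#' @param n_points Number of grid points including t = 0 (>= 2).
#' @param init Initial state; defaults to [initial_state()] of the network.
#' @param rtol,atol Solver tolerances (relative; absolute in uM).
#' @param cons_tol Allowed drift of each conserved total, uM (also applied
#'   relative to the initial total).
#' @return Object of class `rho_trajectory`: list with `times` (min),
#'   `states` (n_points x 11 matrix, uM), `network`, and `solver_info`
#'   (success flag, tolerances, step diagnostics).
#' @export
simulate_trajectory <- function(network, t_end = 600, n_points = 601,
                                init = NULL, rtol = 1e-8, atol = 1e-10,
                                cons_tol = 1e-6) {
  stopifnot(inherits(network, "rho_network"))
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0",
                                             call. = FALSE)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  if (is.null(init)) init <- initial_state(network)
  init <- init[network$species]
  times <- seq(0, t_end, length.out = n_points)
  rhs <- assemble_rhs(network)
  out <- deSolve::lsoda(y = init, times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  diagn <- attributes(out)
  if (!is.null(diagn$istate) && diagn$istate[1] < 0) {
    stop("numerical error: integrator failed (istate = ",
         diagn$istate[1], ") at t ~ ", max(out[, "time"]), " min",
         call. = FALSE)
  }
  states <- out[, network$species, drop = FALSE]
  if (any(states < -1e-8)) {
    stop("numerical-integrity error: concentration below -1e-8 uM (min = ",
         signif(min(states), 4), ")", call. = FALSE)
  }
  states[states < 0] <- 0
  rownames(states) <- NULL
  totals0 <- conserved_totals(init)
  for (i in seq_len(nrow(states))) {
    drift <- abs(conserved_totals(states[i, ]) - totals0)
    lim <- pmax(cons_tol, cons_tol * abs(totals0))
    if (any(drift > lim)) {
      stop("numerical-integrity error: conserved total drifted by ",
           signif(max(drift), 4), " uM at t = ", times[i], " min",
           call. = FALSE)
    }
  }
  structure(list(times = times, states = states, network = network,
                 solver_info = list(success = TRUE, method = "lsoda",
                                    rtol = rtol, atol = atol,
                                    istate = diagn$istate,
                                    rstate = diagn$rstate)),
            class = "rho_trajectory")
}

#' @export
print.rho_trajectory <- function(x, ...) {
  n <- length(x$times)
  act <- x$states[, x$network$readout]
  cat("Rho cycle trajectory: ", n, " points over [0, ",
      max(x$times), "] min\n", sep = "")
  cat(sprintf("  activation ([GTP-Rho/Effector], uM): peak %.4g at t = %.4g, final %.4g\n",
              max(act), x$times[which.max(act)], act[n]))
  invisible(x)
}

#' Relax the unstimulated system to steady state
#'
#' Integrates the stimulus-free system in doubling windows until the
#' right-hand side falls below `tol` in max-norm, up to a relaxation
#' horizon of `max_time` minutes. Idempotent: re-running from the result
#' returns the same state. The stimulus must be absent (the decaying
#' stimulus makes "steady state" ill-defined otherwise).
#'
#' @param network A [rho_network()].
#' @param seed Starting state; defaults to the analytic binding-equilibrium
#'   seed used by [initial_state()].
#' @param tol Convergence criterion on `max |d/dt|`, uM/min.
#' @param max_time Total relaxation horizon budget, min.
#' @return Named steady-state concentration vector, uM.
#' @export
steady_state <- function(network, seed = NULL, tol = 1e-10,
                         max_time = 10000) {
  stopifnot(inherits(network, "rho_network"))
  if (is.null(seed)) seed <- initial_state(network, add_stimulus = FALSE)
  seed <- seed[network$species]
  if (seed[["Stimulus"]] > 0) {
    stop("steady_state requires a stimulus-free state", call. = FALSE)
  }
  rhs <- assemble_rhs(network)
  maxdot <- function(y) max(abs(rhs(0, y, NULL)[[1]]))
  y <- seed
  elapsed <- 0
  window <- 100
  while (maxdot(y) >= tol) {
    if (elapsed >= max_time) {
      stop("numerical error: steady state not reached within ", max_time,
           " min of relaxation (max |d/dt| = ", signif(maxdot(y), 4),
           " uM/min)", call. = FALSE)
    }
    window <- min(window, max_time - elapsed)
    out <- deSolve::lsoda(y = y, times = c(0, window), func = rhs,
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    y <- out[nrow(out), network$species]
    y[y < 0] <- 0
    elapsed <- elapsed + window
    window <- window * 2
  }
  y
}

#' Write a trajectory to CSV
#'
#' One row per time point; first column `time_min`, then one column per
#' species in the canonical species order, concentrations in uM.
#'
#' @param traj A `rho_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "rho_trajectory"))
  df <- data.frame(time_min = traj$times, traj$states, check.names = FALSE)
  names(df) <- c("time_min", paste0(colnames(traj$states), "_uM"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
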