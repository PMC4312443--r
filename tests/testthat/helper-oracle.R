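# Independent fixed-step 4th-order Runge-Kutta integrator, used as the
# oracle against the adaptive solver. Steps at `dt` and records the state
# at each requested output time (which must be multiples of dt).
rk4_integrate <- function(rhs, y0, t_end, dt, t_out) {
  n_steps <- round(t_end / dt)
  record <- integer(0)
  out <- matrix(NA_real_, nrow = length(t_out), ncol = length(y0),
                dimnames = list(NULL, names(y0)))
  idx <- round(t_out / dt)
  y <- y0
  if (any(idx == 0)) out[idx == 0, ] <- y
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * dt
    k1 <- rhs(t, y, NULL)[[1]]
    k2 <- rhs(t + dt / 2, y + dt / 2 * k1, NULL)[[1]]
    k3 <- rhs(t + dt / 2, y + dt / 2 * k2, NULL)[[1]]
    k4 <- rhs(t + dt, y + dt * k3, NULL)[[1]]
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    hit <- which(idx == i)
    if (length(hit)) out[hit, ] <- y
  }
  out
}

# Random non-negative states over the 11 species, seeded.
random_states <- function(n, seed = 42, scale = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    stats::setNames(stats::runif(11, 0, scale), rho_species())
  })
}

# Shared baseline objects, computed once per test run.
baseline_env <- new.env()
baseline_fig1 <- function() {
  if (is.null(baseline_env$fig1)) {
    baseline_env$fig1 <- fig_variant_timecourses()
  }
  baseline_env$fig1
}
baseline_summaries <- function() {
  s <- baseline_fig1()$summaries
  rownames(s) <- s$variant
  s
}
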