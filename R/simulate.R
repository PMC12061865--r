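#' Simulation settings
#'
#' Protocol settings of the stochastic simulations. Defaults follow the
#' published protocol: Euler-Maruyama with a 0.1 ms step, 7 s of simulated
#' time, the first 1 s discarded as transient, gating noise amplitude 0.01,
#' and 100 replicates per condition.
#'
#' @param dt integration step in seconds (default `1e-4`, i.e. 0.1 ms).
#' @param duration total simulated time in seconds.
#' @param transient initial stretch (seconds) discarded before averaging.
#' @param sigma noise amplitude on the gating variables (nA).
#' @param n_reps number of stochastic replicates.
#' @param base_seed integer seed; replicate `r` uses `base_seed + r`.
#' @return A list of class `"simulation_settings"`.
#' @export
simulation_settings <- function(dt = 1e-4, duration = 7, transient = 1,
                                sigma = 0.01, n_reps = 100, base_seed = 42L) {
  if (!(dt > 0 && dt <= transient && transient < duration))
    stop("simulation_settings: need 0 < dt <= transient < duration",
         call. = FALSE)
  if (sigma < 0) stop("simulation_settings: sigma must be >= 0",
                      call. = FALSE)
  if (n_reps < 1) stop("simulation_settings: n_reps must be >= 1",
                       call. = FALSE)
  s <- list(dt = dt, duration = duration, transient = transient,
            sigma = sigma, n_reps = as.integer(n_reps),
            base_seed = as.integer(base_seed))
  class(s) <- "simulation_settings"
  s
}

n_steps_of <- function(settings) {
  list(total = as.integer(round(settings$duration / settings$dt)),
       transient = as.integer(round(settings$transient / settings$dt)))
}

# Flatten a sero_model_params object into the 58-value vector consumed by the
# compiled integrator (29 per region; see src/integrator.cpp for the layout).
flatten_params <- function(mp) {
  stopifnot(inherits(mp, "sero_model_params"))
  blk <- function(p, kin) {
    fac <- inflammation_factors(mp$inflammation, kin)
    c(p$I_thr_E, p$I_thr_I, p$g_E, p$g_I, p$d_E, p$d_I, p$J_NMDA, p$J,
      p$w_plus, p$W_E, p$W_I, p$W5HT_E, p$W5HT_I, p$R, p$Io,
      p$tau_NMDA, p$tau_GABA, p$gamma, p$C_in, p$serotonergic_sign,
      fac[["X1"]], fac[["X2"]],
      kin$alpha, kin$C_BR, kin$Vmax, kin$Km, kin$tau_5HT, kin$J_5HT,
      kin$beta)
  }
  c(blk(mp$pfc, mp$kinetics$pfc), blk(mp$scc, mp$kinetics$scc))
}

#' Single Euler-Maruyama step
#'
#' Advance the 8-dimensional state by one step: the gating variables receive
#' the deterministic drift plus `sigma*sqrt(dt)` times a standard normal
#' draw; the serotonergic current and serotonin concentration are advanced
#' deterministically. Clamps are applied after the update: `S_E` to the unit
#' interval, `S_I` and the concentrations to nonnegative values.
#'
#' This reference implementation is written in plain R on top of
#' [drift_field()]; production runs use the compiled loop inside
#' [run_trajectory()], which the test suite cross-checks against this step.
#'
#' @param state numeric state vector of length 8.
#' @param mp a [model_params()] object.
#' @param dt step size (seconds).
#' @param sigma noise amplitude.
#' @param noise four standard normal draws, ordered (S_E PFC, S_I PFC,
#'   S_E SCC, S_I SCC). Drawn from the session RNG when omitted.
#' @return The updated state vector.
#' @export
em_step <- function(state, mp, dt, sigma, noise = stats::rnorm(4)) {
  stopifnot(length(state) == 8L, length(noise) == 4L, dt > 0)
  d8 <- drift_field(state, mp)
  s <- state + dt * d8
  idx <- c(1L, 2L, 5L, 6L)
  s[idx] <- s[idx] + sigma * sqrt(dt) * noise
  s[c(1L, 5L)] <- pmin(pmax(s[c(1L, 5L)], 0), 1)
  s[c(2L, 6L)] <- pmax(s[c(2L, 6L)], 0)
  s[c(4L, 8L)] <- pmax(s[c(4L, 8L)], 0)
  bad <- which(!is.finite(s))
  if (length(bad))
    stop("em_step: state variable '", state_names()[bad[1L]],
         "' became non-finite", call. = FALSE)
  names(s) <- state_names()
  s
}

#' Random initial state
#'
#' Draw the random initial conditions used by [run_trajectory()]:
#' gating variables uniform on (0, 0.5), serotonergic current uniform on
#' (0, 1), serotonin concentration uniform on (40, 80) nM. The ranges
#' bracket the operating regime; the discarded transient absorbs the choice.
#'
#' @return Named state vector of length 8.
#' @export
random_initial_state <- function() {
  s <- numeric(8L)
  for (k in 0:1) {
    i <- k * 4L
    s[i + 1L] <- stats::runif(1, 0, 0.5)
    s[i + 2L] <- stats::runif(1, 0, 0.5)
    s[i + 3L] <- stats::runif(1, 0, 1)
    s[i + 4L] <- stats::runif(1, 40, 80)
  }
  names(s) <- state_names()
  s
}

#' Integrate one stochastic trajectory
#'
#' Run a full Euler-Maruyama trajectory from random initial conditions and
#' return time-averages of the post-transient serotonin concentration and
#' population rates per region.
#'
#' @param mp a [model_params()] object.
#' @param settings a [simulation_settings()] object.
#' @param seed integer seed for this trajectory (initial conditions and
#'   noise).
#' @param record keep the sampled trajectory (thinned) in the result.
#' @param thin recording interval in steps when `record = TRUE`.
#' @param init optional fixed initial state (bypasses the random draw).
#' @return A list of class `"trajectory_summary"` with elements `serotonin`,
#'   `rate_E`, `rate_I` (each named `c(pfc=, scc=)`), `final_state`,
#'   `n_retained`, and optionally `trajectory`.
#' @export
run_trajectory <- function(mp, settings = simulation_settings(), seed = 1L,
                           record = FALSE, thin = 100L, init = NULL) {
  stopifnot(inherits(mp, "sero_model_params"),
            inherits(settings, "simulation_settings"))
  ns <- n_steps_of(settings)
  set.seed(as.integer(seed))
  state0 <- if (is.null(init)) random_initial_state() else init
  res <- .em_integrate_cpp(flatten_params(mp), as.numeric(state0),
                           settings$dt, ns$total, ns$transient,
                           settings$sigma, record, as.integer(thin))
  out <- list(
    serotonin = c(pfc = res$mean_conc[1L], scc = res$mean_conc[2L]),
    rate_E = c(pfc = res$mean_r_E[1L], scc = res$mean_r_E[2L]),
    rate_I = c(pfc = res$mean_r_I[1L], scc = res$mean_r_I[2L]),
    final_state = stats::setNames(res$final_state, state_names()),
    n_retained = res$n_retained,
    seed = as.integer(seed))
  if (record) {
    colnames(res$trajectory) <- c("time", state_names())
    out$trajectory <- res$trajectory
  }
  class(out) <- "trajectory_summary"
  out
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat("<trajectory_summary>\n")
  cat(sprintf("  serotonin (nM): PFC %.2f  SCC %.2f\n",
              x$serotonin[["pfc"]], x$serotonin[["scc"]]))
  cat(sprintf("  rate_E (Hz):    PFC %.3f  SCC %.3f\n",
              x$rate_E[["pfc"]], x$rate_E[["scc"]]))
  cat(sprintf("  retained steps: %d (seed %d)\n", x$n_retained, x$seed))
  invisible(x)
}

#' Replicate a condition and summarize
#'
#' Run `n_reps` independent trajectories (replicate `r` seeded with
#' `base_seed + r`) and aggregate the per-replicate time-averages into means
#' and standard errors per region and observable.
#'
#' @inheritParams run_trajectory
#' @param observables which observables to keep in the summary table.
#' @return A data frame of class `"condition_summary"` with columns
#'   `region`, `observable`, `mean`, `sem`, `n`.
#' @export
run_replicates <- function(mp, settings = simulation_settings(),
                           observables = c("serotonin", "rate_E")) {
  stopifnot(inherits(mp, "sero_model_params"),
            inherits(settings, "simulation_settings"))
  reps <- vector("list", settings$n_reps)
  for (r in seq_len(settings$n_reps)) {
    reps[[r]] <- tryCatch(
      run_trajectory(mp, settings, seed = settings$base_seed + r),
      error = function(e)
        stop("run_replicates: replicate ", r, " failed: ",
             conditionMessage(e), call. = FALSE))
  }
  rows <- list()
  for (obs in observables) {
    for (reg in c("pfc", "scc")) {
      vals <- vapply(reps, function(tr) tr[[obs]][[reg]], numeric(1L))
      sem <- if (length(vals) > 1L)
        stats::sd(vals) / sqrt(length(vals)) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        region = toupper(reg), observable = obs,
        mean = mean(vals), sem = sem, n = length(vals),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "base_seed") <- settings$base_seed
  class(out) <- c("condition_summary", class(out))
  out
}

#' Deterministic steady state of the coupled system
#'
#' Noise-free fixed point of the full 8-dimensional drift, used as the test
#' oracle for the stochastic simulations. The solver relaxes the
#' deterministic system from a fixed interior state and then polishes the
#' root with a damped Newton iteration on a finite-difference Jacobian.
#'
#' @param mp a [model_params()] object.
#' @param tol absolute tolerance on every drift component.
#' @param max_iter Newton iteration cap.
#' @return Named state vector at the fixed point, with the residual drift
#'   norm in attribute `"residual"` and the rates in attribute `"rates"`.
#' @export
steady_state_oracle <- function(mp, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(mp, "sero_model_params"), tol > 0)
  # deterministic relaxation for a good starting point (20 s of model time)
  relax <- .em_integrate_cpp(flatten_params(mp),
                             as.numeric(system_state()),
                             1e-3, 20000L, 19999L, 0, FALSE, 1L)
  s <- relax$final_state
  scale <- pmax(abs(s), 1e-3)
  f <- drift_field(s, mp)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) break
    Jm <- matrix(0, 8L, 8L)
    for (j in 1:8) {
      h <- 1e-7 * scale[j]
      sp <- s; sp[j] <- sp[j] + h
      sm <- s; sm[j] <- sm[j] - h
      Jm[, j] <- (drift_field(sp, mp) - drift_field(sm, mp)) / (2 * h)
    }
    step <- tryCatch(solve(Jm, -f), error = function(e) NULL)
    if (is.null(step))
      stop("steady_state_oracle: singular Jacobian at residual ",
           format(max(abs(f))), call. = FALSE)
    lambda <- 1
    repeat {
      s_new <- s + lambda * step
      f_new <- drift_field(s_new, mp)
      if (max(abs(f_new)) < max(abs(f)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    s <- s_new
    f <- f_new
  }
  if (max(abs(f)) >= tol)
    stop("steady_state_oracle: no convergence within ", max_iter,
         " iterations; residual ", format(max(abs(f))), call. = FALSE)
  names(s) <- state_names()
  attr(s, "residual") <- max(abs(f))
  attr(s, "rates") <- state_rates(s, mp)
  s
}
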