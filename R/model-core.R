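#' Population transfer function
#'
#' Static nonlinearity mapping a population input current to a firing rate,
#' `H(I) = g*(I - I_thr) / (1 - exp(-d*g*(I - I_thr)))`. The singularity at
#' `I = I_thr` is removable; the analytic limit `1/d` is used when
#' `|d*g*(I - I_thr)| < 1e-6`. The function is continuous, strictly
#' increasing in `I` and nonnegative.
#'
#' @param I input current (nA); may be a vector.
#' @param g gain slope (nC^-1).
#' @param d curvature gain (dimensionless).
#' @param I_thr threshold current (nA).
#' @return Firing rate(s) in Hz.
#' @export
#' @examples
#' transfer_rate(0.4, 310, 0.16, 0.4)    # 1/d = 6.25 Hz at threshold
#' transfer_rate(0.42, 310, 0.16, 0.4)   # 9.854 Hz
transfer_rate <- function(I, g, d, I_thr) {
  if (!all(is.finite(I)) || !all(is.finite(c(g, d, I_thr))))
    stop("transfer_rate: non-finite input", call. = FALSE)
  if (g <= 0 || d <= 0)
    stop("transfer_rate: g and d must be strictly positive", call. = FALSE)
  x <- g * (I - I_thr)
  dx <- d * x
  r <- ifelse(abs(dx) < 1e-6, 1 / d, x / (1 - exp(-dx)))
  r
}

#' Cytokine modulation factors on serotonin synthesis and reuptake
#'
#' Computes the multiplicative factors `X1` (synthesis attenuation via
#' tryptophan diversion into the kynurenine pathway) and `X2` (reuptake
#' enhancement via transporter upregulation):
#' `X1 = c1^m / (c1^m + theta * B * degree^m)`,
#' `X2 = 1 + c2 * theta * B * degree`,
#' where `theta` is the Heaviside gate on cytokine elevation: 0 when
#' `degree <= 1` (control), 1 otherwise. The anti-inflammatory blocker
#' `B < 1` attenuates the cytokine term; `B = 1` recovers the untreated
#' expressions.
#'
#' @param cond an [inflammation_condition()].
#' @param kin a [kinetics_params()] (supplies `c1`, `m`, `c2`).
#' @return Named numeric vector `c(X1 = ..., X2 = ...)` with
#'   `0 < X1 <= 1` and `X2 >= 1`.
#' @export
#' @examples
#' inflammation_factors(inflammation_condition(degree = 1))        # c(1, 1)
#' inflammation_factors(inflammation_condition(degree = 2.3))
inflammation_factors <- function(cond, kin) {
  stopifnot(inherits(cond, "inflammation_condition"),
            inherits(kin, "kinetics_params"))
  theta <- as.numeric(cond$degree > 1)
  c1m <- kin$c1^kin$m
  X1 <- c1m / (c1m + theta * cond$B * cond$degree^kin$m)
  X2 <- 1 + kin$c2 * theta * cond$B * cond$degree
  c(X1 = X1, X2 = X2)
}

#' Regional input currents
#'
#' Assemble the excitatory and inhibitory population input currents of one
#' region from its own state, its incoming long-range excitation, and the
#' serotonergic current. The serotonergic terms enter with the region's
#' receptor sign: positive in PFC (excitatory 5HT2A) and negative in SCC
#' (inhibitory 5HT1A). The long-range term appears only in the excitatory
#' current.
#'
#' @param S_E,S_I synaptic gating variables of the region.
#' @param M serotonergic current variable of the region.
#' @param params the region's [region_params()].
#' @param S_E_other excitatory gating variable of the other region.
#' @return Named numeric vector `c(I_E = ..., I_I = ...)` in nA.
#' @export
region_currents <- function(S_E, S_I, M, params, S_E_other) {
  p <- params
  sgn <- p$serotonergic_sign
  I_E <- p$w_plus * p$J_NMDA * S_E - p$J * S_I +
    sgn * p$W5HT_E * p$R * M + p$W_E * p$Io +
    p$J_NMDA * p$C_in * S_E_other
  I_I <- p$J_NMDA * S_E - S_I + sgn * p$W5HT_I * p$R * M + p$W_I * p$Io
  c(I_E = unname(I_E), I_I = unname(I_I))
}

#' Synaptic gating drift
#'
#' Deterministic drift of the NMDA and GABA gating variables:
#' `dS_E/dt = -S_E/tau_NMDA + (1 - S_E)*gamma*r_E` and
#' `dS_I/dt = -S_I/tau_GABA + r_I`, with time in seconds and rates in Hz.
#' Noise is added by the integrator, not here.
#'
#' @param S_E,S_I gating variables.
#' @param r_E,r_I population rates (Hz), nonnegative.
#' @param params the region's [region_params()].
#' @return Named numeric vector `c(dS_E = ..., dS_I = ...)` (per second).
#' @export
gating_derivatives <- function(S_E, S_I, r_E, r_I, params) {
  if (r_E < 0 || r_I < 0)
    stop("gating_derivatives: rates must be nonnegative", call. = FALSE)
  c(dS_E = unname(-S_E / params$tau_NMDA + (1 - S_E) * params$gamma * r_E),
    dS_I = unname(-S_I / params$tau_GABA + r_I))
}

#' Serotonergic current drift
#'
#' `tau_5HT * dM/dt = -M + J_5HT / (1 + exp(-beta*(conc + 1)))`. The
#' equilibrium value lies in `(0, J_5HT)` and increases with the serotonin
#' concentration. The sigmoid argument carries the additive 1 nM offset of
#' the published formulation.
#'
#' @param M serotonergic current variable.
#' @param conc extracellular serotonin concentration (nM), nonnegative.
#' @param kin a [kinetics_params()].
#' @return dM/dt (per second).
#' @export
serotonergic_current_derivative <- function(M, conc, kin) {
  if (conc < 0)
    stop("serotonergic_current_derivative: conc must be nonnegative",
         call. = FALSE)
  (-M + kin$J_5HT / (1 + exp(-kin$beta * (conc + 1)))) / kin$tau_5HT
}

#' Serotonin concentration drift
#'
#' Michaelis-Menten kinetics of extracellular serotonin:
#' `d[5HT]/dt = alpha*C_BR*r_E*X1 - Vmax*conc/(Km + conc)*X2` (nM/s).
#' Synthesis is linear in the excitatory rate and attenuated by `X1`;
#' reuptake saturates in the concentration and is enhanced by `X2`.
#'
#' @param r_E excitatory population rate (Hz), nonnegative.
#' @param conc extracellular serotonin (nM), nonnegative.
#' @param X1,X2 modulation factors from [inflammation_factors()].
#' @param kin a [kinetics_params()].
#' @return d(conc)/dt in nM/s.
#' @export
serotonin_derivative <- function(r_E, conc, X1, X2, kin) {
  if (conc < 0 || r_E < 0)
    stop("serotonin_derivative: conc and r_E must be nonnegative",
         call. = FALSE)
  kin$alpha * kin$C_BR * r_E * X1 - kin$Vmax * conc / (kin$Km + conc) * X2
}

#' Closed-form serotonin fixed point at a fixed excitatory rate
#'
#' With the rate held at `r_E` and factors `X1`, `X2` fixed, the zero of the
#' serotonin drift is `conc* = Km*u / (1 - u)` with
#' `u = alpha*C_BR*r_E*X1 / (Vmax*X2)`, valid for `u < 1`.
#'
#' @inheritParams serotonin_derivative
#' @return Fixed-point concentration (nM).
#' @export
serotonin_fixed_point <- function(r_E, X1, X2, kin) {
  u <- kin$alpha * kin$C_BR * r_E * X1 / (kin$Vmax * X2)
  if (u >= 1)
    stop("serotonin_fixed_point: synthesis exceeds maximal reuptake (u >= 1)",
         call. = FALSE)
  kin$Km * u / (1 - u)
}

#' Full deterministic drift field
#'
#' Drift of the coupled 8-dimensional system (per second), in the state
#' layout `(S_E, S_I, M, conc)` for PFC then SCC. This is the noise-free
#' right-hand side integrated by [em_step()] and zeroed by
#' [steady_state_oracle()].
#'
#' @param state numeric state vector of length 8 (see [system_state()]).
#' @param mp a [model_params()] object.
#' @return Named numeric vector of length 8.
#' @export
drift_field <- function(state, mp) {
  stopifnot(inherits(mp, "sero_model_params"), length(state) == 8L)
  out <- numeric(8L)
  regions <- list(mp$pfc, mp$scc)
  kins <- list(mp$kinetics$pfc, mp$kinetics$scc)
  for (k in 1:2) {
    p <- regions[[k]]
    kin <- kins[[k]]
    i <- (k - 1L) * 4L
    io <- (2L - k) * 4L
    fac <- inflammation_factors(mp$inflammation, kin)
    cur <- region_currents(state[i + 1L], state[i + 2L], state[i + 3L], p,
                           state[io + 1L])
    r_E <- transfer_rate(cur[["I_E"]], p$g_E, p$d_E, p$I_thr_E)
    r_I <- transfer_rate(cur[["I_I"]], p$g_I, p$d_I, p$I_thr_I)
    gd <- gating_derivatives(state[i + 1L], state[i + 2L],
                             max(r_E, 0), max(r_I, 0), p)
    out[i + 1L] <- gd[["dS_E"]]
    out[i + 2L] <- gd[["dS_I"]]
    out[i + 3L] <- serotonergic_current_derivative(state[i + 3L],
                                                   max(state[i + 4L], 0), kin)
    out[i + 4L] <- serotonin_derivative(max(r_E, 0), max(state[i + 4L], 0),
                                        fac[["X1"]], fac[["X2"]], kin)
  }
  names(out) <- state_names()
  out
}

#' Population rates at a state
#'
#' Evaluate the excitatory and inhibitory transfer functions of both regions
#' at a given state.
#'
#' @inheritParams drift_field
#' @return Named vector `c(r_E_pfc, r_I_pfc, r_E_scc, r_I_scc)` in Hz.
#' @export
state_rates <- function(state, mp) {
  stopifnot(inherits(mp, "sero_model_params"), length(state) == 8L)
  regions <- list(mp$pfc, mp$scc)
  out <- numeric(4L)
  for (k in 1:2) {
    p <- regions[[k]]
    i <- (k - 1L) * 4L
    io <- (2L - k) * 4L
    cur <- region_currents(state[i + 1L], state[i + 2L], state[i + 3L], p,
                           state[io + 1L])
    out[(k - 1L) * 2L + 1L] <- transfer_rate(cur[["I_E"]], p$g_E, p$d_E,
                                             p$I_thr_E)
    out[(k - 1L) * 2L + 2L] <- transfer_rate(cur[["I_I"]], p$g_I, p$d_I,
                                             p$I_thr_I)
  }
  names(out) <- c("r_E_pfc", "r_I_pfc", "r_E_scc", "r_I_scc")
  out
}
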