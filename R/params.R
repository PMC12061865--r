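#' Neural region parameters
#'
#' Construct the parameter set of one regional excitatory/inhibitory
#' mean-field subnetwork. Defaults reproduce the published values for the
#' prefrontal cortex (PFC) and subcallosal cingulate cortex (SCC)
#' subnetworks; see [default_params()] for the assembled two-region model.
#'
#' Internally all time constants are stored in seconds and currents in nA.
#' The NMDA kinetic parameter `gamma` follows the convention in which the
#' excitatory gating fixed point is `gamma*tau_NMDA*r/(1 + gamma*tau_NMDA*r)`
#' with the rate `r` in Hz, i.e. `gamma = 0.641` when `tau_NMDA = 0.1` s.
#'
#' @param region `"PFC"` or `"SCC"`. Determines the sign of the serotonergic
#'   current: excitatory (5HT2A-dominated, +1) in PFC, inhibitory
#'   (5HT1A-dominated, -1) in SCC.
#' @param I_thr_E,I_thr_I firing threshold currents (nA).
#' @param g_E,g_I gain slopes of the transfer functions (nC^-1).
#' @param d_E,d_I curvature gains of the transfer functions (dimensionless).
#' @param J_NMDA excitatory synaptic coupling (nA).
#' @param J local feedback synaptic coupling (dimensionless).
#' @param w_plus recurrent excitation weight.
#' @param W_E,W_I weights of the external input onto the excitatory and
#'   inhibitory populations.
#' @param W5HT_E,W5HT_I weights of the serotonergic input onto the excitatory
#'   and inhibitory populations.
#' @param R serotonergic receptor density (dimensionless scale).
#' @param Io external input current (nA).
#' @param tau_NMDA,tau_GABA synaptic gating time constants (seconds).
#' @param gamma NMDA kinetic parameter (see Details).
#' @param C_in incoming long-range coupling constant (scales the other
#'   region's excitatory gating variable in this region's excitatory current).
#'
#' @return A list of class `"region_params"`.
#' @export
#' @examples
#' p <- region_params("PFC")
#' p$serotonergic_sign  # +1, 5HT2A excitatory
region_params <- function(region = c("PFC", "SCC"),
                          I_thr_E = 0.4, I_thr_I = 0.286,
                          g_E = 310, g_I = 615,
                          d_E = 0.16, d_I = 0.087,
                          J_NMDA = if (region == "PFC") 0.15 else 0.33,
                          J = 1.135,
                          w_plus = 1.4,
                          W_E = 1,
                          W_I = if (region == "PFC") 0.7 else 0.8,
                          W5HT_E = if (region == "PFC") 0.48 else 0.19,
                          W5HT_I = if (region == "PFC") 0.47 else 0.19,
                          R = 0.6,
                          Io = if (region == "PFC") 0.32 else 0.45,
                          tau_NMDA = 0.1, tau_GABA = 0.01,
                          gamma = 0.641,
                          C_in = if (region == "PFC") 0.01 else 0.005) {
  region <- match.arg(region)
  p <- list(
    region = region,
    I_thr_E = I_thr_E, I_thr_I = I_thr_I,
    g_E = g_E, g_I = g_I, d_E = d_E, d_I = d_I,
    J_NMDA = J_NMDA, J = J, w_plus = w_plus,
    W_E = W_E, W_I = W_I, W5HT_E = W5HT_E, W5HT_I = W5HT_I,
    R = R, Io = Io,
    tau_NMDA = tau_NMDA, tau_GABA = tau_GABA, gamma = gamma,
    C_in = C_in,
    serotonergic_sign = if (region == "PFC") 1 else -1
  )
  class(p) <- "region_params"
  validate_region_params(p)
  p
}

validate_region_params <- function(p) {
  num <- c("I_thr_E", "I_thr_I", "g_E", "g_I", "d_E", "d_I", "J_NMDA", "J",
           "w_plus", "W_E", "W_I", "W5HT_E", "W5HT_I", "R", "Io",
           "tau_NMDA", "tau_GABA", "gamma", "C_in")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("region_params: field '", f, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  pos <- c("g_E", "g_I", "d_E", "d_I", "J_NMDA", "J", "w_plus", "W_E", "W_I",
           "W5HT_E", "W5HT_I", "R", "tau_NMDA", "tau_GABA", "gamma")
  for (f in pos)
    if (p[[f]] <= 0)
      stop("region_params: field '", f, "' must be strictly positive",
           call. = FALSE)
  if (!p$serotonergic_sign %in% c(-1, 1))
    stop("region_params: serotonergic_sign must be +1 or -1", call. = FALSE)
  if ((p$region == "PFC") != (p$serotonergic_sign == 1))
    stop("region_params: serotonergic_sign must be +1 iff region is PFC",
         call. = FALSE)
  invisible(p)
}

#' Serotonin kinetics parameters
#'
#' Parameters of the serotonergic current and of serotonin
#' synthesis/reuptake kinetics. Defaults reproduce the published values; the
#' synthesis shape constant `c1` differs between regions (5 in PFC, 4 in SCC).
#'
#' @param alpha dimensionless scale of the synthesis drive.
#' @param C_BR raphe-to-cortex fiber density (dimensionless).
#' @param Vmax maximal Michaelis-Menten reuptake rate (nM/s).
#' @param Km Michaelis constant of reuptake (nM); 170 under control, raised to
#'   200 by SSRI treatment.
#' @param tau_5HT time constant of the serotonergic current (seconds).
#' @param J_5HT range of the serotonergic current (dimensionless).
#' @param beta slope of the serotonergic-current sigmoid (nM^-1).
#' @param c1 shape constant of the cytokine effect on synthesis.
#' @param m steepness of the cytokine effect on synthesis.
#' @param c2 increment of the cytokine effect on reuptake.
#'
#' @return A list of class `"kinetics_params"`.
#' @export
kinetics_params <- function(alpha = 5, C_BR = 15, Vmax = 1300, Km = 170,
                            tau_5HT = 0.12, J_5HT = 1, beta = 0.008,
                            c1 = 5, m = 2, c2 = 0.019) {
  k <- list(alpha = alpha, C_BR = C_BR, Vmax = Vmax, Km = Km,
            tau_5HT = tau_5HT, J_5HT = J_5HT, beta = beta,
            c1 = c1, m = m, c2 = c2)
  class(k) <- "kinetics_params"
  validate_kinetics_params(k)
  k
}

validate_kinetics_params <- function(k) {
  for (f in names(unclass(k))) {
    v <- k[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("kinetics_params: field '", f,
           "' must be a strictly positive finite scalar", call. = FALSE)
  }
  invisible(k)
}

#' Inflammation condition
#'
#' The degree of inflammation is the fold-elevation of the TNF-alpha cytokine
#' concentration over its basal value, `degree = cyt / cyt_b`. It can be given
#' directly (the study grid uses 1, 1.25, 1.4 and 2.3 for control, mild,
#' moderate and severe inflammation) or derived from the two concentrations.
#' The blocker factor `B` (0 < B <= 1) scales the cytokine term inside the
#' synthesis and reuptake modulation factors; `B = 1` means no
#' anti-inflammatory treatment.
#'
#' @param degree degree of inflammation (dimensionless, >= 0). Ignored when
#'   both `cyt` and `cyt_b` are supplied.
#' @param B anti-inflammatory blocker factor in (0, 1].
#' @param cyt,cyt_b optional TNF-alpha concentrations (pg/mL) from which the
#'   degree is computed.
#'
#' @return A list of class `"inflammation_condition"` with fields `degree`,
#'   `B`, and (when supplied) `cyt`, `cyt_b`.
#' @export
#' @examples
#' inflammation_condition(degree = 2.3)
#' inflammation_condition(cyt = 6.19, cyt_b = 2.69)$degree  # 2.301...
inflammation_condition <- function(degree = 1, B = 1,
                                   cyt = NULL, cyt_b = NULL) {
  if (!is.null(cyt) && !is.null(cyt_b))
    degree <- degree_of_inflammation(cyt, cyt_b)
  if (!is.numeric(degree) || length(degree) != 1L || !is.finite(degree) ||
      degree < 0)
    stop("inflammation_condition: degree must be a finite scalar >= 0",
         call. = FALSE)
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B <= 0 || B > 1)
    stop("inflammation_condition: B must lie in (0, 1]", call. = FALSE)
  cond <- list(degree = degree, B = B, cyt = cyt, cyt_b = cyt_b)
  class(cond) <- "inflammation_condition"
  cond
}

#' Full model parameter set
#'
#' Bundle the two regional subnetworks, their serotonin kinetics, and the
#' inflammation condition into a single model parameter object, the input of
#' [run_trajectory()], [run_replicates()] and [steady_state_oracle()].
#'
#' @param pfc,scc `region_params` for the two regions.
#' @param kinetics_pfc,kinetics_scc `kinetics_params` per region (only the
#'   synthesis shape `c1` differs between regions by default).
#' @param inflammation an `inflammation_condition`.
#'
#' @return A list of class `"sero_model_params"`.
#' @export
model_params <- function(pfc = region_params("PFC"),
                         scc = region_params("SCC"),
                         kinetics_pfc = kinetics_params(c1 = 5),
                         kinetics_scc = kinetics_params(c1 = 4),
                         inflammation = inflammation_condition()) {
  stopifnot(inherits(pfc, "region_params"), inherits(scc, "region_params"),
            inherits(kinetics_pfc, "kinetics_params"),
            inherits(kinetics_scc, "kinetics_params"),
            inherits(inflammation, "inflammation_condition"))
  if (pfc$region != "PFC" || scc$region != "SCC")
    stop("model_params: pfc/scc arguments have swapped regions", call. = FALSE)
  mp <- list(pfc = pfc, scc = scc,
             kinetics = list(pfc = kinetics_pfc, scc = kinetics_scc),
             inflammation = inflammation)
  class(mp) <- "sero_model_params"
  mp
}

#' Default model parameters
#'
#' The published parameter set: control condition (degree of inflammation 1,
#' no treatment, `Km = 170` nM, `B = 1`).
#'
#' @return A `"sero_model_params"` object.
#' @export
default_params <- function() model_params()

#' @export
print.sero_model_params <- function(x, ...) {
  cat("<sero_model_params>\n")
  cat(sprintf("  inflammation: degree = %g, B = %g\n",
              x$inflammation$degree, x$inflammation$B))
  cat(sprintf("  reuptake Km:  PFC %g nM, SCC %g nM\n",
              x$kinetics$pfc$Km, x$kinetics$scc$Km))
  cat(sprintf("  receptor R:   PFC %g, SCC %g\n", x$pfc$R, x$scc$R))
  cat(sprintf("  tau_NMDA:     PFC %g s, SCC %g s\n",
              x$pfc$tau_NMDA, x$scc$tau_NMDA))
  invisible(x)
}

#' @export
print.region_params <- function(x, ...) {
  cat(sprintf("<region_params: %s (serotonergic sign %+d)>\n",
              x$region, x$serotonergic_sign))
  flds <- setdiff(names(unclass(x)), c("region", "serotonergic_sign"))
  cat(paste(sprintf("  %-9s %g", flds, unlist(x[flds])), collapse = "\n"),
      "\n")
  invisible(x)
}

# State vector layout used throughout: named length-8 numeric,
# (S_E, S_I, M, conc) for PFC then SCC.
state_names <- function() {
  c("S_E_pfc", "S_I_pfc", "M_pfc", "conc_pfc",
    "S_E_scc", "S_I_scc", "M_scc", "conc_scc")
}

#' Construct a system state vector
#'
#' @param S_E_pfc,S_I_pfc,M_pfc,conc_pfc PFC gating variables, serotonergic
#'   current variable and extracellular serotonin concentration (nM).
#' @param S_E_scc,S_I_scc,M_scc,conc_scc the same for SCC.
#' @return Named numeric vector of length 8.
#' @export
system_state <- function(S_E_pfc = 0.2, S_I_pfc = 0.05, M_pfc = 0.6,
                         conc_pfc = 60,
                         S_E_scc = 0.2, S_I_scc = 0.05, M_scc = 0.6,
                         conc_scc = 60) {
  s <- c(S_E_pfc, S_I_pfc, M_pfc, conc_pfc,
         S_E_scc, S_I_scc, M_scc, conc_scc)
  if (!all(is.finite(s))) stop("system_state: non-finite entry", call. = FALSE)
  names(s) <- state_names()
  s
}
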