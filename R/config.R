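#' Read a parameter configuration file
#'
#' Load a YAML configuration with sections `pfc`, `scc`, `serotonin`,
#' `inflammation` and `simulation`. The file carries values in the printed
#' units of the original parameter tables (time constants in ms, the NMDA
#' kinetic parameter in its per-ms convention, `dt` in ms); the loader
#' converts them to the package's internal frame (seconds, Hz, nM, nA).
#' The shipped default, `system.file("extdata", "default_params.yaml",
#' package = "immunosero")`, reproduces the published tables exactly.
#'
#' @param path path to a YAML file.
#' @return A list with elements `params` (a [model_params()] object) and
#'   `settings` (a [simulation_settings()] object).
#' @export
read_param_config <- function(path) {
  if (!file.exists(path))
    stop("read_param_config: no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- c("pfc", "scc", "serotonin", "inflammation", "simulation")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("read_param_config: missing section(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  reg <- function(sec, region) {
    region_params(
      region = region,
      I_thr_E = sec$I_thr_E, I_thr_I = sec$I_thr_I,
      g_E = sec$g_E, g_I = sec$g_I, d_E = sec$d_E, d_I = sec$d_I,
      J_NMDA = sec$J_NMDA, J = sec$J, w_plus = sec$w_plus,
      W_E = sec$W_E, W_I = sec$W_I,
      W5HT_E = sec$W5HT_E, W5HT_I = sec$W5HT_I,
      R = sec$R, Io = sec$Io,
      tau_NMDA = sec$tau_NMDA_ms / 1000,
      tau_GABA = sec$tau_GABA_ms / 1000,
      gamma = sec$gamma_per_ms * 1000,
      C_in = sec$C_in)
  }
  ser <- cfg$serotonin
  kin <- function(c1) {
    kinetics_params(alpha = ser$alpha, C_BR = ser$C_BR, Vmax = ser$Vmax,
                    Km = ser$Km, tau_5HT = ser$tau_5HT_ms / 1000,
                    J_5HT = ser$J_5HT, beta = ser$beta,
                    c1 = c1, m = ser$m, c2 = ser$c2)
  }
  infl <- inflammation_condition(degree = cfg$inflammation$degree,
                                 B = cfg$inflammation$B)
  sim <- cfg$simulation
  list(
    params = model_params(pfc = reg(cfg$pfc, "PFC"),
                          scc = reg(cfg$scc, "SCC"),
                          kinetics_pfc = kin(ser$c1_pfc),
                          kinetics_scc = kin(ser$c1_scc),
                          inflammation = infl),
    settings = simulation_settings(dt = sim$dt_ms / 1000,
                                   duration = sim$duration_s,
                                   transient = sim$transient_s,
                                   sigma = sim$sigma,
                                   n_reps = sim$n_reps,
                                   base_seed = sim$base_seed))
}

#' Write a parameter configuration file
#'
#' Inverse of [read_param_config()]: serialize a parameter set and
#' simulation settings to YAML in printed units, so that reading the file
#' back reproduces them exactly.
#'
#' @param params a [model_params()] object.
#' @param settings a [simulation_settings()] object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_param_config <- function(params, settings, path) {
  stopifnot(inherits(params, "sero_model_params"),
            inherits(settings, "simulation_settings"))
  reg <- function(p) {
    list(I_thr_E = p$I_thr_E, I_thr_I = p$I_thr_I,
         g_E = p$g_E, g_I = p$g_I, d_E = p$d_E, d_I = p$d_I,
         J_NMDA = p$J_NMDA, J = p$J, w_plus = p$w_plus,
         W_E = p$W_E, W_I = p$W_I,
         W5HT_E = p$W5HT_E, W5HT_I = p$W5HT_I,
         R = p$R, Io = p$Io,
         tau_NMDA_ms = p$tau_NMDA * 1000,
         tau_GABA_ms = p$tau_GABA * 1000,
         gamma_per_ms = p$gamma / 1000,
         C_in = p$C_in)
  }
  kp <- params$kinetics$pfc
  ks <- params$kinetics$scc
  cfg <- list(
    pfc = reg(params$pfc),
    scc = reg(params$scc),
    serotonin = list(alpha = kp$alpha, C_BR = kp$C_BR, Vmax = kp$Vmax,
                     Km = kp$Km, tau_5HT_ms = kp$tau_5HT * 1000,
                     J_5HT = kp$J_5HT, beta = kp$beta,
                     c1_pfc = kp$c1, c1_scc = ks$c1, m = kp$m, c2 = kp$c2),
    inflammation = list(degree = params$inflammation$degree,
                        B = params$inflammation$B),
    simulation = list(dt_ms = settings$dt * 1000,
                      duration_s = settings$duration,
                      transient_s = settings$transient,
                      sigma = settings$sigma,
                      n_reps = settings$n_reps,
                      base_seed = settings$base_seed))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Default configuration file path
#'
#' @return Path of the shipped default YAML configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_params.yaml", package = "immunosero")
}
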