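#' Degree of inflammation from cytokine concentrations
#'
#' Ratio of the TNF-alpha concentration under inflammation to its basal
#' value, the model's scalar index of inflammation severity.
#'
#' @param cyt TNF-alpha concentration (pg/mL), nonnegative.
#' @param cyt_b basal TNF-alpha concentration (pg/mL), strictly positive.
#' @return `cyt / cyt_b` (dimensionless).
#' @export
#' @examples
#' degree_of_inflammation(3.35, 2.69)  # ~1.25, mild inflammation
#' degree_of_inflammation(6.19, 2.69)  # ~2.3, severe inflammation
degree_of_inflammation <- function(cyt, cyt_b) {
  if (!is.numeric(cyt) || !is.numeric(cyt_b) || any(!is.finite(cyt)) ||
      any(!is.finite(cyt_b)))
    stop("degree_of_inflammation: inputs must be finite numerics",
         call. = FALSE)
  if (any(cyt_b <= 0))
    stop("degree_of_inflammation: cyt_b must be > 0", call. = FALSE)
  if (any(cyt < 0))
    stop("degree_of_inflammation: cyt must be >= 0", call. = FALSE)
  cyt / cyt_b
}

#' Treatment specification
#'
#' Drug treatments enter the model as parameter edits: SSRIs lower the
#' affinity of serotonin for its transporter (`Km` 170 -> 200 nM);
#' anti-inflammatory blockade attenuates the cytokine term in the synthesis
#' and reuptake factors (`B` 1 -> 0.55); the combined treatment applies both.
#'
#' @param name one of `"none"`, `"ssri"`, `"antiinflammatory"`, `"combined"`.
#' @return A list of class `"treatment_spec"` with fields `name`, `Km`, `B`.
#' @export
treatment_spec <- function(name = c("none", "ssri", "antiinflammatory",
                                    "combined")) {
  name <- match.arg(name)
  spec <- switch(name,
    none = list(Km = 170, B = 1),
    ssri = list(Km = 200, B = 1),
    antiinflammatory = list(Km = 170, B = 0.55),
    combined = list(Km = 200, B = 0.55))
  spec$name <- name
  class(spec) <- "treatment_spec"
  spec
}

#' Apply a drug treatment to a parameter set
#'
#' Returns a copy of the model parameters with the reuptake `Km` (both
#' regions) and the blocker factor `B` overwritten according to the
#' treatment; the input object is not modified.
#'
#' @param mp a [model_params()] object.
#' @param spec a [treatment_spec()] or a treatment name.
#' @return A new `"sero_model_params"` object.
#' @export
apply_treatment <- function(mp, spec) {
  stopifnot(inherits(mp, "sero_model_params"))
  if (is.character(spec)) spec <- treatment_spec(spec)
  if (!inherits(spec, "treatment_spec"))
    stop("apply_treatment: unknown treatment specification", call. = FALSE)
  mp$kinetics$pfc$Km <- spec$Km
  mp$kinetics$scc$Km <- spec$Km
  mp$inflammation$B <- spec$B
  mp
}

#' Variant specification
#'
#' Two mechanistic model variants beyond the baseline: an NMDA
#' excitotoxicity variant (quinolinic-acid-mediated NMDA activation,
#' modelled as a 5% increase of the SCC NMDA time constant) and a
#' postsynaptic receptor-density reduction variant (an 8% reduction of the
#' receptor density parameter `R`, the compensatory change reported in
#' depressed individuals).
#'
#' @param name one of `"baseline"`, `"nmda_excitotoxicity"`,
#'   `"receptor_reduction"`.
#' @param tau_NMDA_scale_SCC multiplier on the SCC NMDA time constant for
#'   the excitotoxicity variant.
#' @param R_scale multiplier on the receptor density for the
#'   receptor-reduction variant.
#' @return A list of class `"variant_spec"`.
#' @export
variant_spec <- function(name = c("baseline", "nmda_excitotoxicity",
                                  "receptor_reduction"),
                         tau_NMDA_scale_SCC = 1.05, R_scale = 0.92) {
  name <- match.arg(name)
  if (tau_NMDA_scale_SCC <= 0 || R_scale <= 0)
    stop("variant_spec: scales must be positive", call. = FALSE)
  spec <- list(name = name, tau_NMDA_scale_SCC = tau_NMDA_scale_SCC,
               R_scale = R_scale)
  class(spec) <- "variant_spec"
  spec
}

#' Apply a model variant to a parameter set
#'
#' `"nmda_excitotoxicity"` multiplies the SCC NMDA time constant by
#' `tau_NMDA_scale_SCC` (PFC untouched). `"receptor_reduction"` multiplies
#' the SCC receptor density `R` by `R_scale`; the reduction models the lower
#' postsynaptic 5HT1A density reported in the SCC of depressed individuals,
#' and scoping it to SCC leaves PFC outputs essentially unchanged (the test
#' suite verifies this insensitivity). `"baseline"` returns the parameters
#' unchanged.
#'
#' @param mp a [model_params()] object.
#' @param spec a [variant_spec()] or a variant name.
#' @return A new `"sero_model_params"` object.
#' @export
apply_variant <- function(mp, spec) {
  stopifnot(inherits(mp, "sero_model_params"))
  if (is.character(spec)) spec <- variant_spec(spec)
  if (!inherits(spec, "variant_spec"))
    stop("apply_variant: unknown variant specification", call. = FALSE)
  switch(spec$name,
    baseline = mp,
    nmda_excitotoxicity = {
      mp$scc$tau_NMDA <- mp$scc$tau_NMDA * spec$tau_NMDA_scale_SCC
      mp
    },
    receptor_reduction = {
      mp$scc$R <- mp$scc$R * spec$R_scale
      mp
    })
}

degree_table <- function() {
  data.frame(
    degree_label = c("control", "mild", "moderate", "severe"),
    degree = c(1, 1.25, 1.4, 2.3),
    stringsAsFactors = FALSE)
}

#' Parameter set for one experimental condition
#'
#' Assemble the effective parameters of a (degree, treatment, variant)
#' condition from a base parameter set.
#'
#' @param degree degree of inflammation (numeric) or one of the labels
#'   `"control"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param treatment treatment name or [treatment_spec()].
#' @param variant variant name or [variant_spec()].
#' @param base base parameter set, default [default_params()].
#' @return A `"sero_model_params"` object.
#' @export
#' @examples
#' mp <- condition_params("severe", "combined")
#' mp$inflammation$degree  # 2.3
condition_params <- function(degree = 1, treatment = "none",
                             variant = "baseline",
                             base = default_params()) {
  if (is.character(degree)) {
    tab <- degree_table()
    i <- match(degree, tab$degree_label)
    if (is.na(i)) stop("condition_params: unknown degree label '", degree,
                       "'", call. = FALSE)
    degree <- tab$degree[i]
  }
  mp <- base
  mp$inflammation <- inflammation_condition(degree = degree,
                                            B = mp$inflammation$B)
  mp <- apply_treatment(mp, treatment)
  mp <- apply_variant(mp, variant)
  mp
}

#' Full condition grid
#'
#' Enumerate the study's experimental grid: for each of the three variants
#' (baseline, NMDA excitotoxicity, receptor reduction), all four degrees of
#' inflammation crossed with all four treatments — 48 conditions in a
#' deterministic order (treatment varies fastest, then degree, then
#' variant), starting with (control, none, baseline).
#'
#' @return A data frame with columns `degree_label`, `degree`, `treatment`,
#'   `variant`.
#' @export
build_condition_grid <- function() {
  degrees <- degree_table()
  treatments <- c("none", "ssri", "antiinflammatory", "combined")
  variants <- c("baseline", "nmda_excitotoxicity", "receptor_reduction")
  grid <- expand.grid(treatment = treatments,
                      degree_label = degrees$degree_label,
                      variant = variants,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$degree <- degrees$degree[match(grid$degree_label,
                                      degrees$degree_label)]
  grid[, c("degree_label", "degree", "treatment", "variant")]
}
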