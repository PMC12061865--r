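#' Battery configuration
#'
#' Configuration of a simulation battery over the condition grid.
#'
#' @param settings a [simulation_settings()] object.
#' @param degrees subset of degree labels to run (`NULL` = all).
#' @param treatments subset of treatment names (`NULL` = all).
#' @param variants subset of variant names (`NULL` = all).
#' @param out_dir optional output directory; when given, [run_battery()]
#'   writes a tidy CSV of results and a JSON provenance file there.
#' @param base base parameter set for every condition.
#' @param verbose log per-condition progress to the console.
#' @return A list of class `"battery_config"`.
#' @export
battery_config <- function(settings = simulation_settings(),
                           degrees = NULL, treatments = NULL,
                           variants = NULL, out_dir = NULL,
                           base = default_params(), verbose = FALSE) {
  grid <- build_condition_grid()
  chk <- function(sel, pool, what) {
    if (is.null(sel)) return(unique(pool))
    bad <- setdiff(sel, pool)
    if (length(bad))
      stop("battery_config: unknown ", what, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    sel
  }
  cfg <- list(settings = settings,
              degrees = chk(degrees, grid$degree_label, "degree labels"),
              treatments = chk(treatments, grid$treatment, "treatments"),
              variants = chk(variants, grid$variant, "variants"),
              out_dir = out_dir, base = base, verbose = isTRUE(verbose))
  class(cfg) <- "battery_config"
  cfg
}

#' Run a simulation battery
#'
#' Execute [run_replicates()] for every condition selected by the
#' configuration and bind the summaries into one tidy table. Every condition
#' uses the same `base_seed`, so the output is reproducible and invariant to
#' the order in which conditions are run. When `out_dir` is set, a CSV of the
#' table and a JSON provenance record (settings, seed, effective per-condition
#' parameters, package version) are written.
#'
#' @param config a [battery_config()] object.
#' @return A data frame (`"result_table"`) with columns `condition`,
#'   `degree`, `treatment`, `variant`, `region`, `observable`, `mean`,
#'   `sem`, `n`, `seed`.
#' @export
run_battery <- function(config = battery_config()) {
  stopifnot(inherits(config, "battery_config"))
  grid <- build_condition_grid()
  grid <- grid[grid$degree_label %in% config$degrees &
                 grid$treatment %in% config$treatments &
                 grid$variant %in% config$variants, , drop = FALSE]
  if (nrow(grid) == 0L)
    stop("run_battery: empty condition selection", call. = FALSE)
  rows <- vector("list", nrow(grid))
  params_log <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    id <- paste(g$degree_label, g$treatment, g$variant, sep = "/")
    if (config$verbose)
      message(sprintf("[battery] %-45s (seed %d)", id,
                      config$settings$base_seed))
    mp <- condition_params(g$degree_label, g$treatment, g$variant,
                           base = config$base)
    summ <- tryCatch(
      run_replicates(mp, config$settings),
      error = function(e)
        stop("run_battery: condition '", id, "' failed: ",
             conditionMessage(e), call. = FALSE))
    summ$condition <- g$degree_label
    summ$degree <- g$degree
    summ$treatment <- g$treatment
    summ$variant <- g$variant
    summ$seed <- config$settings$base_seed
    rows[[i]] <- as.data.frame(summ)[, c("condition", "degree", "treatment",
                                         "variant", "region", "observable",
                                         "mean", "sem", "n", "seed")]
    params_log[[i]] <- list(condition = id, degree = g$degree,
                            Km = mp$kinetics$pfc$Km,
                            B = mp$inflammation$B,
                            tau_NMDA_scc = mp$scc$tau_NMDA,
                            R_pfc = mp$pfc$R, R_scc = mp$scc$R)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("result_table", class(out))
  if (!is.null(config$out_dir))
    write_results(out, config, params_log)
  out
}

#' Write battery results and provenance
#'
#' @param table a result table from [run_battery()].
#' @param config the [battery_config()] that produced it.
#' @param params_log optional per-condition effective-parameter records.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(table, config, params_log = NULL) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(config$out_dir, "results.csv")
  utils::write.csv(as.data.frame(table), csv, row.names = FALSE)
  prov <- list(
    package = "immunosero",
    version = as.character(utils::packageVersion("immunosero")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    settings = unclass(config$settings),
    degrees = config$degrees, treatments = config$treatments,
    variants = config$variants,
    conditions = params_log)
  js <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(prov, js, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(csv = csv, json = js))
}

#' Published reference summary values
#'
#' The published per-condition means and sems (serotonin in nM, excitatory
#' population rate in Hz) shipped with the package for regression
#' comparison. Only conditions with printed values are present; variant rows
#' cover the SCC observables the original analyses report.
#'
#' @return A data frame with columns `condition`, `treatment`, `variant`,
#'   `region`, `observable`, `mean`, `sem`, `label`.
#' @export
reference_values <- function() {
  path <- system.file("extdata", "reference_values.csv",
                      package = "immunosero")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Compare a result table against reference values
#'
#' Row-by-row relative comparison of a battery result table against a
#' reference table on the keys (`condition`, `treatment`, `variant`,
#' `region`, `observable`).
#'
#' @param table a result table from [run_battery()].
#' @param reference a reference table (default [reference_values()]).
#' @param rel_tol relative tolerance for a row to pass.
#' @return A data frame of class `"comparison_report"` with the merged rows,
#'   their relative deviations and pass flags; summary counts are stored in
#'   attributes `n_pass`, `n_fail`, `max_rel_dev`.
#' @export
compare_to_reference <- function(table, reference = reference_values(),
                                 rel_tol = 0.1) {
  keys <- c("condition", "treatment", "variant", "region", "observable")
  for (k in keys) {
    if (!k %in% names(table)) stop("compare_to_reference: results lack key '",
                                   k, "'", call. = FALSE)
    if (!k %in% names(reference))
      stop("compare_to_reference: reference lacks key '", k, "'",
           call. = FALSE)
  }
  m <- merge(reference, as.data.frame(table), by = keys,
             suffixes = c("_ref", ""))
  missing <- nrow(reference) - nrow(m)
  if (missing > 0) {
    anti <- reference[!do.call(paste, reference[keys]) %in%
                        do.call(paste, m[keys]), keys]
    stop("compare_to_reference: ", missing,
         " reference rows have no matching result row, e.g. ",
         paste(unlist(anti[1, ]), collapse = "/"), call. = FALSE)
  }
  m$rel_dev <- abs(m$mean - m$mean_ref) / abs(m$mean_ref)
  m$pass <- m$rel_dev <= rel_tol
  attr(m, "n_pass") <- sum(m$pass)
  attr(m, "n_fail") <- sum(!m$pass)
  attr(m, "max_rel_dev") <- max(m$rel_dev)
  attr(m, "rel_tol") <- rel_tol
  class(m) <- c("comparison_report", class(m))
  m
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report: %d pass, %d fail at rel_tol %.3g; max dev %.3g>\n",
              attr(x, "n_pass"), attr(x, "n_fail"), attr(x, "rel_tol"),
              attr(x, "max_rel_dev")))
  if (attr(x, "n_fail") > 0) {
    bad <- as.data.frame(x)[!x$pass,
                            c("condition", "treatment", "variant", "region",
                              "observable", "mean_ref", "mean", "rel_dev")]
    print(bad, row.names = FALSE)
  }
  invisible(x)
}

#' Assess restoration of serotonin and activity to control levels
#'
#' For each treated condition in a result table, decide whether the
#' observable has been restored to the untreated control (degree 1) level of
#' the same variant and region. Serotonin restoration is one-sided — the
#' deficit is corrected when the mean is not meaningfully below control
#' (overshoot counts as restored); activity restoration is two-sided.
#' "Meaningfully" is `max(2*(sem + sem_control), rel_floor*control_mean)`:
#' the sem band widened by a relative floor, since replicate sems of
#' time-averaged observables can be far tighter than a clinically sensible
#' notion of "control level".
#'
#' @param table a result table from [run_battery()] containing the untreated
#'   control rows of each variant present.
#' @param rel_floor relative tolerance floor (default 0.05).
#' @return The treated rows of `table` with extra columns `control_mean`,
#'   `control_sem`, `tol`, `restored`.
#' @export
assess_restoration <- function(table, rel_floor = 0.05) {
  tab <- as.data.frame(table)
  ctrl <- tab[tab$condition == "control" & tab$treatment == "none", ]
  if (nrow(ctrl) == 0L)
    stop("assess_restoration: table lacks untreated control rows",
         call. = FALSE)
  trt <- tab[!(tab$condition == "control" & tab$treatment == "none"), ]
  key <- function(d) paste(d$variant, d$region, d$observable)
  i <- match(key(trt), key(ctrl))
  if (anyNA(i))
    stop("assess_restoration: missing control rows for some variants",
         call. = FALSE)
  trt$control_mean <- ctrl$mean[i]
  trt$control_sem <- ctrl$sem[i]
  trt$tol <- pmax(2 * (trt$sem + trt$control_sem),
                  rel_floor * abs(trt$control_mean))
  trt$restored <- ifelse(
    trt$observable == "serotonin",
    trt$mean >= trt$control_mean - trt$tol,
    abs(trt$mean - trt$control_mean) <= trt$tol)
  trt
}
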