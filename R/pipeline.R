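#' Read and validate a tidy viability table
#'
#' Reads plate records from CSV and enforces the schema used throughout:
#' columns `cell_line`, `drug_a`, `conc_a_uM`, `drug_b`, `conc_b_uM`,
#' `time_h`, `replicate`, `viability_pct`. Optional `conc_a_unit` /
#' `conc_b_unit` columns (values `"uM"` or `"mM"`) are honoured: mM rows are
#' converted to uM and the unit columns dropped. Negative concentrations or
#' viabilities and duplicate (arm, time, replicate) keys are rejected with
#' the offending row indices.
#'
#' @param path CSV path.
#' @return Validated `data.frame` of plate records (concentrations in uM).
#' @export
read_viability_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_line", "drug_a", "conc_a_uM", "drug_b", "conc_b_uM",
                "time_h", "replicate", "viability_pct")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  for (side in c("a", "b")) {
    ucol <- paste0("conc_", side, "_unit")
    ccol <- paste0("conc_", side, "_uM")
    if (ucol %in% names(d)) {
      bad <- which(!d[[ucol]] %in% c("uM", "mM"))
      if (length(bad)) {
        stop("unrecognised ", ucol, " values at rows: ",
             paste(utils::head(bad, 10), collapse = ", "))
      }
      d[[ccol]] <- ifelse(d[[ucol]] == "mM", d[[ccol]] * 1000, d[[ccol]])
      d[[ucol]] <- NULL
    }
  }
  neg <- which(d$conc_a_uM < 0 | d$conc_b_uM < 0 | d$viability_pct < 0)
  if (length(neg)) {
    stop("negative concentration or viability at rows: ",
         paste(utils::head(neg, 10), collapse = ", "))
  }
  key <- interaction(d$cell_line, d$drug_a, d$conc_a_uM, d$drug_b,
                     d$conc_b_uM, d$time_h, d$replicate, drop = TRUE)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (arm, time, replicate) keys at rows: ",
         paste(utils::head(dup, 10), collapse = ", "))
  }
  d
}

#' Interpret an interaction parameter estimate
#'
#' Labels a psi estimate as synergistic, additive or antagonistic relative
#' to 1 with an equivalence band: additive when `|psi - 1| <= band`,
#' synergistic when `psi < 1 - band`, antagonistic when `psi > 1 + band`.
#'
#' @param psi Estimated interaction parameter (> 0).
#' @param band Equivalence half-width around 1 (default 0.1).
#' @return `"synergistic"`, `"additive"` or `"antagonistic"`.
#' @export
#' @examples
#' interpret_psi(2.2)            # antagonistic
#' interpret_psi(0.95)           # additive at the default band
#' interpret_psi(0.95, band = 0.01)  # synergistic
interpret_psi <- function(psi, band = 0.1) {
  if (psi <= 0) stop("psi must be > 0")
  if (band < 0) stop("band must be >= 0")
  if (abs(psi - 1) <= band) "additive"
  else if (psi < 1) "synergistic"
  else "antagonistic"
}

#' Pipeline run configuration
#'
#' @param cell_line `"Huh7"` or `"MDA-MB-468"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for dataset simulation.
#' @param noise A [noise_model()] (its seed field is overridden by `seed`).
#' @param band Psi equivalence band for [interpret_psi()].
#' @param static_csv,timecourse_csv Optional paths to existing tidy viability
#'   tables; when `NULL` the datasets are simulated from the published
#'   parameter estimates.
#' @param write_plots Write the response-surface PNG (default `TRUE`).
#' @return An object of class `run_config`.
#' @export
pipeline_config <- function(cell_line, out_dir, seed = 1,
                            noise = noise_model(0, 0), band = 0.1,
                            static_csv = NULL, timecourse_csv = NULL,
                            write_plots = TRUE) {
  .check_cell_line(cell_line)
  stopifnot(inherits(noise, "noise_model"))
  for (p in c(static_csv, timecourse_csv)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  structure(list(cell_line = cell_line, out_dir = out_dir,
                 seed = as.integer(seed), noise = noise, band = band,
                 static_csv = static_csv, timecourse_csv = timecourse_csv,
                 write_plots = write_plots),
            class = "run_config")
}

.stage_log <- function(stage, t0) {
  message(sprintf("[%s] done in %.2f s", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full combination-PD analysis pipeline
#'
#' Executes the sequential workflow on one cell line: (1) simulate (or load)
#' the static 72-h plate and the 0-96 h time-course study; (2) fit the
#' single-agent Hill curves (cisplatin with `r0` and `gamma` fixed,
#' cimetidine with all four parameters free); (3) fix them and estimate the
#' static interaction parameter psi; (4) fit the control growth rate, the
#' single-agent kill models (cisplatin jointly with `kg`; cimetidine with
#' `kg` fixed at the control estimate), fix everything and estimate the
#' time-course psi; (5) classify the observed combination wells against the
#' additive surface and render it. Results (CSV data, JSON fit summaries,
#' classification table, plot, human-readable report) are written under
#' `config$out_dir`; given the same config and seed the outputs are
#' identical.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `analysis_report` (also written to
#'   `report.json` / `report.txt`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cl <- config$cell_line
  noise <- config$noise
  noise$seed <- config$seed
  design <- default_design(cl)

  # stage 1: data
  t0 <- as.numeric(Sys.time())
  if (is.null(config$static_csv)) {
    truth_static <- interaction_params(reference_hill(cl, "CIS"),
                                       reference_hill(cl, "CIM"),
                                       psi = reference_psi(cl, "static"))
    static <- generate_static(design, truth_static, noise)
    write_viability_table(static, file.path(config$out_dir, "static.csv"),
                          meta = list(cell_line = cl, seed = config$seed,
                                      psi = truth_static$psi,
                                      noise = unclass(noise)))
  } else {
    static <- read_viability_table(config$static_csv)
  }
  if (is.null(config$timecourse_csv)) {
    noise_tc <- noise
    noise_tc$seed <- config$seed + 1L
    truth_tc <- reference_pd(cl)
    timecourse <- generate_timecourse(design, truth_tc, noise_tc)
    write_viability_table(timecourse,
                          file.path(config$out_dir, "timecourse.csv"),
                          meta = list(cell_line = cl, seed = noise_tc$seed,
                                      psi = truth_tc$psi,
                                      noise = unclass(noise_tc)))
  } else {
    timecourse <- read_viability_table(config$timecourse_csv)
  }
  .stage_log("data", t0)

  # stage 2: single-agent concentration-response fits
  t0 <- as.numeric(Sys.time())
  t_end <- design$endpoint_time
  fit_cis <- fit_hill(as_single_agent(static, "CIS", t_end))
  fit_cim <- fit_hill(as_single_agent(static, "CIM", t_end),
                      fit_spec(free = c("r0", "imax", "ic50", "gamma")))
  hill_cis <- hill_params(r0 = fit_cis$fixed$r0, imax = fit_cis$estimates["imax"],
                          ic50 = fit_cis$estimates["ic50"],
                          gamma = fit_cis$fixed$gamma)
  hill_cim <- do.call(hill_params, as.list(fit_cim$estimates))
  .stage_log("hill fits", t0)

  # stage 3: static interaction
  t0 <- as.numeric(Sys.time())
  fit_static_psi <- fit_interaction_static(as_combination(static, t_end),
                                           hill_cis, hill_cim)
  psi_static <- unname(fit_static_psi$estimates["psi"])
  .stage_log("static psi", t0)

  # stage 4: time-course PD fits (sequential: control -> singles -> combo)
  t0 <- as.numeric(Sys.time())
  fit_kg <- fit_growth(as_control(timecourse))
  kg_hat <- unname(fit_kg$estimates["kg"])
  fit_cis_pd <- fit_pd_single(as_single_agent(timecourse, "CIS"))
  fit_cim_pd <- fit_pd_single(
    as_single_agent(timecourse, "CIM"),
    fit_spec(free = c("smax", "sc50", "tau"),
             fixed = list(r0 = 100, kg = kg_hat)))
  pd_fixed <- pd_system_params(
    kg = unname(fit_cis_pd$estimates["kg"]), r0 = 100,
    cis = pd_agent_params(smax = unname(fit_cis_pd$estimates["smax"]),
                          sc50 = unname(fit_cis_pd$estimates["sc50"]),
                          tau = unname(fit_cis_pd$estimates["tau"])),
    cim = pd_agent_params(smax = unname(fit_cim_pd$estimates["smax"]),
                          sc50 = unname(fit_cim_pd$estimates["sc50"]),
                          tau = unname(fit_cim_pd$estimates["tau"])))
  fit_tc_psi <- fit_pd_combo(as_combination(timecourse), pd_fixed)
  psi_tc <- unname(fit_tc_psi$estimates["psi"])
  .stage_log("time-course PD", t0)

  # stage 5: surface classification
  t0 <- as.numeric(Sys.time())
  cls <- classify_points(hill_cis, hill_cim, as_combination(static, t_end))
  utils::write.csv(cls$calls,
                   file.path(config$out_dir, "surface_calls.csv"),
                   row.names = FALSE)
  if (config$write_plots) {
    dense <- function(g) exp(seq(log(min(g)), log(max(g)), length.out = 50))
    surf <- build_additive_surface(hill_cis, hill_cim,
                                   dense(design$cis_concs),
                                   dense(design$cim_concs))
    plot_surface(surf, cls$calls,
                 file = file.path(config$out_dir, "surface.png"),
                 main = paste0(cl, ": additive surface (psi = 1)"))
  }
  .stage_log("surface", t0)

  fits <- list(hill_cis = fit_cis, hill_cim = fit_cim,
               psi_static = fit_static_psi, growth = fit_kg,
               pd_cis = fit_cis_pd, pd_cim = fit_cim_pd,
               psi_timecourse = fit_tc_psi)
  report <- structure(list(
    cell_line = cl,
    psi_static = psi_static,
    psi_static_label = interpret_psi(psi_static, config$band),
    psi_timecourse = psi_tc,
    psi_timecourse_label = interpret_psi(psi_tc, config$band),
    band = config$band,
    surface_summary = cls$summary,
    fits = fits,
    provenance = list(seed = config$seed,
                      noise = unclass(config$noise),
                      package_version = as.character(
                        utils::packageVersion("combopd")))
  ), class = "analysis_report")

  fit_tab <- function(f) {
    list(estimates = as.list(f$estimates), rse_pct = as.list(f$rse_pct),
         rss = f$objective, n_obs = f$n_obs, converged = f$converged)
  }
  jsonlite::write_json(
    c(report[c("cell_line", "psi_static", "psi_static_label",
               "psi_timecourse", "psi_timecourse_label", "band",
               "surface_summary", "provenance")],
      list(fits = lapply(fits, fit_tab))),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(config$out_dir, "report.txt"))
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Combination PD analysis:", x$cell_line, "\n")
  cat(sprintf("  static psi      : %.4f  [%s, band %.2g]\n",
              x$psi_static, x$psi_static_label, x$band))
  cat(sprintf("  time-course psi : %.4f  [%s, band %.2g]\n",
              x$psi_timecourse, x$psi_timecourse_label, x$band))
  s <- x$surface_summary
  cat(sprintf("  surface calls   : %d/%d above additive surface (%.0f%%)\n",
              s$n_above, s$n, 100 * s$frac_above))
  cat("  fits:\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    est <- paste(sprintf("%s=%.4g", names(f$estimates), f$estimates),
                 collapse = ", ")
    cat(sprintf("    %-14s %s (RSS %.4g, n %d)\n", nm, est, f$objective,
                f$n_obs))
  }
  invisible(x)
}
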