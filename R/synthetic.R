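#' Noise model for synthetic viability data
#'
#' Observed viability is generated as
#' `pred * (1 + N(0, cv^2)) + N(0, sd^2)`, truncated at 0. Values above 100%
#' are legitimate (cells grow) and are not clipped.
#'
#' @param cv_proportional Proportional coefficient of variation (fraction,
#'   default 0.10 — typical plate-reader viability variability).
#' @param sd_additive Additive noise standard deviation in percentage points
#'   (default 2).
#' @param seed Optional integer seed making generation deterministic.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv_proportional = 0.10, sd_additive = 2,
                        seed = NULL) {
  if (cv_proportional < 0) stop("cv_proportional must be >= 0")
  if (sd_additive < 0) stop("sd_additive must be >= 0")
  structure(list(cv = cv_proportional, sd = sd_additive, seed = seed),
            class = "noise_model")
}

.apply_noise <- function(pred, noise, replicates) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  n <- length(pred) * replicates
  pred_rep <- rep(pred, each = replicates)
  v <- pred_rep * (1 + stats::rnorm(n, 0, noise$cv)) +
    stats::rnorm(n, 0, noise$sd)
  pmax(v, 0)
}

#' Default experimental design for one cell line
#'
#' Reproduces the plate layout of the combination study: 6 log-spaced
#' cisplatin concentrations (0.05-25 uM) and 6 log-spaced cimetidine
#' concentrations (50-4000 uM, i.e. 0.05-4 mM) as single agents; the full
#' 6 x 6 = 36 combination grid for the static 72-h endpoint; and for the
#' time courses 4 cisplatin concentrations (0.05-1 uM, the highest levels
#' being excluded because their responses saturate) crossed with the 6
#' cimetidine levels giving 24 combinations, observed at 0, 24, 48, 72 and
#' 96 h in triplicate. Intermediate grid values are log-spaced between the
#' reported endpoints.
#'
#' @param cell_line `"Huh7"` or `"MDA-MB-468"`.
#' @return An object of class `study_design` with fields `cell_line`,
#'   `cis_concs`, `cim_concs`, `combo_pairs` (static 36), `tc_cis_concs`,
#'   `tc_combo_pairs` (time-course 24), `times`, `replicates`,
#'   `endpoint_time`.
#' @export
default_design <- function(cell_line) {
  .check_cell_line(cell_line)
  logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))
  cis <- logspace(0.05, 25, 6)
  cim <- logspace(50, 4000, 6)
  tc_cis <- logspace(0.05, 1, 4)
  structure(list(
    cell_line = cell_line,
    cis_concs = cis,
    cim_concs = cim,
    combo_pairs = expand.grid(conc_a = cis, conc_b = cim,
                              KEEP.OUT.ATTRS = FALSE),
    tc_cis_concs = tc_cis,
    tc_combo_pairs = expand.grid(conc_a = tc_cis, conc_b = cim,
                                 KEEP.OUT.ATTRS = FALSE),
    times = c(0, 24, 48, 72, 96),
    replicates = 3,
    endpoint_time = 72
  ), class = "study_design")
}

# Expand per-well predictions into replicate-level tidy records; noise is
# applied afterwards in one seeded pass.
.record_frame <- function(design, conc_a, conc_b, time_h, pred) {
  reps <- design$replicates
  data.frame(
    cell_line = design$cell_line,
    drug_a = "CIS",
    conc_a_uM = rep(conc_a, each = reps),
    drug_b = "CIM",
    conc_b_uM = rep(conc_b, each = reps),
    time_h = rep(time_h, each = reps),
    replicate = rep(seq_len(reps), times = length(pred)),
    viability_pct = rep(pred, each = reps),
    stringsAsFactors = FALSE
  )
}

#' Generate a static endpoint viability dataset
#'
#' Builds the 72-h plate: a control arm, both single-agent dilution series
#' (generated from each drug's own Hill curve) and the full combination grid
#' (generated from the competitive interaction model with the design's psi),
#' with replicate-level noise.
#'
#' @param design A [default_design()] object.
#' @param params An [interaction_params()] object: single-agent Hill
#'   parameters plus the generating psi.
#' @param noise A [noise_model()]; use `noise_model(0, 0)` for noise-free
#'   data.
#' @return Tidy `data.frame` of plate records (columns `cell_line`,
#'   `drug_a`, `conc_a_uM`, `drug_b`, `conc_b_uM`, `time_h`, `replicate`,
#'   `viability_pct`).
#' @export
generate_static <- function(design, params, noise = noise_model()) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "interaction_params"))
  t72 <- design$endpoint_time
  conc_a <- c(0, design$cis_concs, rep(0, length(design$cim_concs)),
              design$combo_pairs$conc_a)
  conc_b <- c(0, rep(0, length(design$cis_concs)), design$cim_concs,
              design$combo_pairs$conc_b)
  pred <- numeric(length(conc_a))
  single_a <- conc_a > 0 & conc_b == 0
  single_b <- conc_b > 0 & conc_a == 0
  both <- conc_a > 0 & conc_b > 0
  pred[conc_a == 0 & conc_b == 0] <- params$r0
  pred[single_a] <- hill_response(params$drug_a, conc_a[single_a])
  pred[single_b] <- hill_response(params$drug_b, conc_b[single_b])
  pred[both] <- competitive_interaction_response(params, conc_a[both],
                                                 conc_b[both])
  out <- .record_frame(design, conc_a, conc_b, t72, pred)
  out$viability_pct <- .apply_noise(pred, noise, design$replicates)
  out
}

#' Generate a time-course viability dataset
#'
#' Builds the 0-96 h study: a control arm (exponential growth), single-agent
#' arms for both drugs at the design concentrations, and the 24 combination
#' arms, all simulated from the cell-level PD model (single agents with
#' psi = 1, combinations with the generating psi in `params`).
#'
#' @inheritParams generate_static
#' @param params A [pd_system_params()] object including the generating psi.
#' @return Tidy `data.frame` of plate records, as in [generate_static()].
#' @export
generate_timecourse <- function(design, params, noise = noise_model()) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "pd_system_params"))
  arms <- rbind(
    data.frame(conc_a = 0, conc_b = 0),
    data.frame(conc_a = design$cis_concs, conc_b = 0),
    data.frame(conc_a = 0, conc_b = design$cim_concs),
    design$tc_combo_pairs
  )
  single <- params
  single$psi <- 1
  rows <- lapply(seq_len(nrow(arms)), function(i) {
    ca <- arms$conc_a[i]; cb <- arms$conc_b[i]
    p <- if (ca > 0 && cb > 0) params else single
    pred <- exp(.pd_log_viability(p, ca, cb, design$times))
    .record_frame(design, rep(ca, length(design$times)),
                  rep(cb, length(design$times)), design$times, pred)
  })
  out <- do.call(rbind, rows)
  pred_all <- out$viability_pct[out$replicate == 1]
  out$viability_pct <- .apply_noise(pred_all, noise, design$replicates)
  out
}

#' Extract a single-agent concentration-response slice from plate records
#'
#' Selects the control and single-agent arms for one drug (the other drug's
#' concentration equal to zero), optionally at one time point, and returns
#' the simple `(conc, viability)` table the fitters consume.
#'
#' @param records Tidy plate records (see [generate_static()]).
#' @param drug `"CIS"` (drug A) or `"CIM"` (drug B).
#' @param time_h Optional time point filter (e.g. 72 for the static
#'   endpoint).
#' @return `data.frame` with columns `conc`, `viability` (and `time`).
#' @export
as_single_agent <- function(records, drug = c("CIS", "CIM"), time_h = NULL) {
  drug <- match.arg(drug)
  if (!is.null(time_h)) records <- records[records$time_h %in% time_h, ]
  if (drug == "CIS") {
    r <- records[records$conc_b_uM == 0, ]
    data.frame(conc = r$conc_a_uM, time = r$time_h,
               viability = r$viability_pct)
  } else {
    r <- records[records$conc_a_uM == 0, ]
    data.frame(conc = r$conc_b_uM, time = r$time_h,
               viability = r$viability_pct)
  }
}

#' Extract combination arms from plate records
#'
#' @inheritParams as_single_agent
#' @return `data.frame` with columns `conc_a`, `conc_b`, `time`,
#'   `viability` for rows where both concentrations are positive.
#' @export
as_combination <- function(records, time_h = NULL) {
  if (!is.null(time_h)) records <- records[records$time_h %in% time_h, ]
  r <- records[records$conc_a_uM > 0 & records$conc_b_uM > 0, ]
  data.frame(conc_a = r$conc_a_uM, conc_b = r$conc_b_uM, time = r$time_h,
             viability = r$viability_pct)
}

#' Extract the untreated control arm from plate records
#'
#' @inheritParams as_single_agent
#' @return `data.frame` with columns `time`, `viability`.
#' @export
as_control <- function(records) {
  r <- records[records$conc_a_uM == 0 & records$conc_b_uM == 0, ]
  data.frame(time = r$time_h, viability = r$viability_pct)
}

#' Write plate records and a metadata sidecar
#'
#' Writes the tidy CSV plus a `<path>.meta.json` sidecar recording the
#' design, generating parameters and seed so a dataset can be regenerated
#' exactly.
#'
#' @param records Tidy plate records.
#' @param path Output CSV path.
#' @param meta Optional list (design, parameters, seed) stored as JSON.
#' @return `path`, invisibly.
#' @export
write_viability_table <- function(records, path, meta = NULL) {
  utils::write.csv(records, path, row.names = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  invisible(path)
}
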