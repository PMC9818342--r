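#' Hill concentration-response parameters
#'
#' Container for the four parameters of the inhibitory Hill function used for
#' static 72-h concentration-response curves: baseline viability `r0` (%),
#' maximal fractional inhibition `imax`, half-maximal inhibitory
#' concentration `ic50` (uM) and Hill coefficient `gamma`.
#'
#' @param r0 Baseline viability in percent of control (> 0).
#' @param imax Maximal fractional inhibition, in (0, 1].
#' @param ic50 Half-maximal inhibitory concentration in uM (> 0).
#' @param gamma Hill coefficient (> 0).
#' @return An object of class `hill_params`.
#' @seealso [hill_response()], [fit_hill()]
#' @export
#' @examples
#' hill_params(r0 = 100, imax = 1, ic50 = 1.96, gamma = 1)
hill_params <- function(r0, imax, ic50, gamma) {
  stopifnot(is.numeric(r0), is.numeric(imax), is.numeric(ic50),
            is.numeric(gamma))
  if (r0 <= 0) stop("r0 must be > 0")
  if (imax <= 0 || imax > 1) stop("imax must be in (0, 1]")
  if (ic50 <= 0) stop("ic50 must be > 0")
  if (gamma <= 0) stop("gamma must be > 0")
  structure(list(r0 = r0, imax = imax, ic50 = ic50, gamma = gamma),
            class = "hill_params")
}

#' Competitive-interaction model parameters
#'
#' Two fixed sets of single-agent Hill parameters plus the interaction term
#' `psi` that scales the potency (IC50) terms in the competitive interaction
#' model. `psi` < 1 indicates synergy, `psi` = 1 additivity and `psi` > 1
#' antagonism. `psi_on` selects whether `psi` scales both drugs' IC50s (the
#' default, as the model equation is written) or only drug A's.
#'
#' @param drug_a,drug_b `hill_params` for the two single agents.
#' @param psi Interaction term (> 0).
#' @param r0 Baseline viability used for combinations (default 100%).
#' @param psi_on `"both"` (default) or `"a"`: which IC50(s) psi multiplies.
#' @return An object of class `interaction_params`.
#' @seealso [competitive_interaction_response()], [fit_interaction_static()]
#' @export
interaction_params <- function(drug_a, drug_b, psi = 1, r0 = 100,
                               psi_on = c("both", "a")) {
  stopifnot(inherits(drug_a, "hill_params"), inherits(drug_b, "hill_params"))
  if (psi <= 0) stop("psi must be > 0")
  if (r0 <= 0) stop("r0 must be > 0")
  psi_on <- match.arg(psi_on)
  structure(list(drug_a = drug_a, drug_b = drug_b, psi = psi, r0 = r0,
                 psi_on = psi_on),
            class = "interaction_params")
}

#' Single-drug cell-kill parameters for the dynamic PD model
#'
#' @param smax Maximal killing rate constant (1/h, > 0).
#' @param sc50 Concentration giving half-maximal kill rate (uM, > 0).
#'   Distinct from the static IC50.
#' @param tau Mean transit time between the three signal-delay compartments
#'   (h, > 0). Reported in the field as the transit rate constant 1/tau.
#' @return An object of class `pd_agent_params`.
#' @seealso [pd_system_params()], [simulate_pd()]
#' @export
pd_agent_params <- function(smax, sc50, tau) {
  stopifnot(is.numeric(smax), is.numeric(sc50), is.numeric(tau))
  if (smax <= 0) stop("smax must be > 0")
  if (sc50 <= 0) stop("sc50 must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(smax = smax, sc50 = sc50, tau = tau),
            class = "pd_agent_params")
}

#' Full parameter set for the cell-level PD model
#'
#' Growth and kill parameters for one cell line: exponential growth rate
#' `kg`, baseline viability `r0`, per-drug kill parameters for cisplatin
#' (`cis`) and cimetidine (`cim`), and the interaction parameter `psi`
#' applied to the cisplatin SC50 in the combination model (psi = 1 recovers
#' the single-agent equations).
#'
#' @param kg First-order growth rate constant (1/h, > 0).
#' @param r0 Baseline viability (%, > 0).
#' @param cis,cim `pd_agent_params` for the two drugs.
#' @param psi Interaction parameter (> 0); 1 for single-agent use.
#' @return An object of class `pd_system_params`.
#' @export
pd_system_params <- function(kg, r0 = 100, cis, cim, psi = 1) {
  stopifnot(inherits(cis, "pd_agent_params"), inherits(cim, "pd_agent_params"))
  if (kg <= 0) stop("kg must be > 0")
  if (r0 <= 0) stop("r0 must be > 0")
  if (psi <= 0) stop("psi must be > 0")
  structure(list(kg = kg, r0 = r0, cis = cis, cim = cim, psi = psi),
            class = "pd_system_params")
}

#' Constant-concentration exposure specification
#'
#' Drug concentrations are assumed constant over the incubation (no
#' degradation or uptake-driven depletion in the medium), so an exposure is
#' fully described by the two concentrations and a duration.
#'
#' @param conc_cis,conc_cim Constant concentrations in uM (>= 0).
#' @param t_end Duration in hours (> 0).
#' @return An object of class `exposure_spec`.
#' @export
exposure_spec <- function(conc_cis = 0, conc_cim = 0, t_end = 96) {
  if (conc_cis < 0 || conc_cim < 0) stop("concentrations must be >= 0")
  if (t_end <= 0) stop("t_end must be > 0")
  structure(list(conc_cis = conc_cis, conc_cim = conc_cim, t_end = t_end),
            class = "exposure_spec")
}

# Published single-agent Hill estimates (72 h), uM. CIS fits fixed r0 = 100
# and gamma = 1; CIM fits estimated all four parameters.
.hill_reference <- list(
  "Huh7" = list(
    CIS = list(r0 = 100, imax = 1,    ic50 = 1.96, gamma = 1),
    CIM = list(r0 = 99.5, imax = 0.99, ic50 = 3190, gamma = 3.12)
  ),
  "MDA-MB-468" = list(
    CIS = list(r0 = 100, imax = 1, ic50 = 0.39, gamma = 1),
    CIM = list(r0 = 97.4, imax = 1, ic50 = 3280, gamma = 1.83)
  )
)

# Published cell-level PD estimates. Transit rate constants 1/tau as
# reported: CIS 1.17 / 0.101 per h, CIM 1.92 / 0.523 per h. SC50,CIM in uM.
.pd_reference <- list(
  "Huh7" = list(kg = 0.011, r0 = 100,
                cis = list(smax = 0.038, sc50 = 4.27,     tau = 1 / 1.17),
                cim = list(smax = 0.106, sc50 = 36886.97, tau = 1 / 1.92),
                psi = 0.96),
  "MDA-MB-468" = list(kg = 0.018, r0 = 100,
                      cis = list(smax = 0.108, sc50 = 2.48,     tau = 1 / 0.101),
                      cim = list(smax = 0.096, sc50 = 21453.95, tau = 1 / 0.523),
                      psi = 2.2)
)

.psi_reference <- list(
  "Huh7" = list(static = 0.95, timecourse = 0.96),
  "MDA-MB-468" = list(static = 1.27, timecourse = 2.2)
)

.check_cell_line <- function(cell_line) {
  if (!cell_line %in% names(.hill_reference)) {
    stop("unknown cell line '", cell_line, "'; expected one of: ",
         paste(names(.hill_reference), collapse = ", "))
  }
  cell_line
}

#' Published single-agent Hill parameter estimates
#'
#' Returns the reported 72-h concentration-response estimates for cisplatin
#' or cimetidine in Huh7 or MDA-MB-468 cells, used throughout as generating
#' truths for synthetic data and as fixed single-agent parameters in
#' interaction fits. IC50 is returned in uM (cimetidine values are mM-range
#' and stored as uM).
#'
#' @param cell_line `"Huh7"` or `"MDA-MB-468"`.
#' @param drug `"CIS"` (cisplatin) or `"CIM"` (cimetidine).
#' @return A [hill_params()] object.
#' @export
#' @examples
#' reference_hill("Huh7", "CIS")$ic50  # 1.96 uM
reference_hill <- function(cell_line, drug = c("CIS", "CIM")) {
  .check_cell_line(cell_line)
  drug <- match.arg(drug)
  do.call(hill_params, .hill_reference[[cell_line]][[drug]])
}

#' Published cell-level PD parameter estimates
#'
#' Reported time-course model estimates (growth rate, per-drug kill
#' parameters and the combination interaction parameter) for one cell line.
#'
#' @param cell_line `"Huh7"` or `"MDA-MB-468"`.
#' @param psi Interaction parameter override; defaults to the reported
#'   time-course estimate (0.96 Huh7, 2.2 MDA-MB-468).
#' @return A [pd_system_params()] object.
#' @export
reference_pd <- function(cell_line, psi = NULL) {
  .check_cell_line(cell_line)
  ref <- .pd_reference[[cell_line]]
  pd_system_params(kg = ref$kg, r0 = ref$r0,
                   cis = do.call(pd_agent_params, ref$cis),
                   cim = do.call(pd_agent_params, ref$cim),
                   psi = if (is.null(psi)) ref$psi else psi)
}

#' Published interaction parameter estimates
#'
#' @param cell_line `"Huh7"` or `"MDA-MB-468"`.
#' @param analysis `"static"` (competitive interaction model at 72 h:
#'   0.95 / 1.27) or `"timecourse"` (cell-level PD model: 0.96 / 2.2).
#' @return The reported psi value.
#' @export
reference_psi <- function(cell_line, analysis = c("static", "timecourse")) {
  .check_cell_line(cell_line)
  analysis <- match.arg(analysis)
  .psi_reference[[cell_line]][[analysis]]
}
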