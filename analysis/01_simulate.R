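#!/usr/bin/env Rscript
# Stage 1: simulate the viability studies for both cell lines.
#
# The original raw plate data are not deposited, so the analysis runs on
# synthetic CCK-8-style datasets generated from the published parameter
# estimates: a static 72-h plate (6 CIS x 6 CIM grid plus single-agent arms,
# triplicate) and a 0-96 h time-course study (single agents plus 24
# combinations). Replicate noise: 10% proportional CV + 2% additive SD.

library(combopd)

seed <- 20260927L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

for (cl in c("Huh7", "MDA-MB-468")) {
  des <- default_design(cl)
  tag <- gsub("-", "", tolower(cl))

  static_truth <- interaction_params(reference_hill(cl, "CIS"),
                                     reference_hill(cl, "CIM"),
                                     psi = reference_psi(cl, "static"))
  static <- generate_static(des, static_truth, noise_model(0.10, 2, seed))
  write_viability_table(static,
                        file.path("results/data", paste0(tag, "_static.csv")),
                        meta = list(cell_line = cl, seed = seed,
                                    psi = static_truth$psi,
                                    endpoint_h = des$endpoint_time))

  tc_truth <- reference_pd(cl)
  tc <- generate_timecourse(des, tc_truth, noise_model(0.10, 2, seed + 1L))
  write_viability_table(tc,
                        file.path("results/data", paste0(tag, "_timecourse.csv")),
                        meta = list(cell_line = cl, seed = seed + 1L,
                                    psi = tc_truth$psi,
                                    times_h = des$times))

  message(sprintf("%s: %d static wells (psi %.2f), %d time-course wells (psi %.2f)",
                  cl, nrow(static), static_truth$psi, nrow(tc), tc_truth$psi))
  seed <- seed + 100L
}
message("wrote results/data/*.csv with .meta.json sidecars")
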