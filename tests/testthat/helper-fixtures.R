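# Shared fixtures: everything is generated in code at test time.

nf <- noise_model(0, 0)

# Noise-free single-agent concentration-response table from a Hill truth.
hill_dataset <- function(truth, concs) {
  data.frame(conc = concs, viability = hill_response(truth, concs))
}

# Random but physiologically plausible parameter draws for property tests.
random_hill <- function() {
  hill_params(r0 = runif(1, 80, 120), imax = runif(1, 0.5, 1),
              ic50 = 10^runif(1, -1, 3), gamma = runif(1, 0.5, 4))
}

random_pd_system <- function(psi = 1) {
  pd_system_params(
    kg = runif(1, 0.005, 0.03), r0 = runif(1, 80, 120),
    cis = pd_agent_params(smax = runif(1, 0.02, 0.15),
                          sc50 = 10^runif(1, -0.5, 1.5),
                          tau = 10^runif(1, -0.3, 1)),
    cim = pd_agent_params(smax = runif(1, 0.02, 0.15),
                          sc50 = 10^runif(1, 2, 4.5),
                          tau = 10^runif(1, -0.3, 1)),
    psi = psi)
}

huh7_static_truth <- function(psi = reference_psi("Huh7", "static")) {
  interaction_params(reference_hill("Huh7", "CIS"),
                     reference_hill("Huh7", "CIM"), psi = psi)
}
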