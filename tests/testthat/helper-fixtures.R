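# Shared fixtures: parameter sets, designs and reduced sampler settings used
# across the test files. All synthetic data are generated in code at test
# time under fixed seeds.

# single balanced population (no influx): closed-form playground
params_single_balanced <- function(alpha = 0.05, N0 = 1e5, chi0 = 0.3,
                                   beta = 1 / 3.1, epsilon = 0.5) {
  kinetic_params(alpha_A = alpha, delta_A = alpha, psi = 1, Phi = 0,
                 N0 = N0, chi0 = chi0, beta = beta, epsilon = epsilon)
}

# spec-style branched recovery truth (fast B, slow A, psi into fast = 0.5)
params_recovery_truth <- function() {
  balance_influx("branched", kinetic_params(
    alpha_A = 0.007, delta_A = 0.012, alpha_B = 0.2, delta_B = 0.25,
    psi = 0.5, epsilon = 0.5, beta = 1 / 3.1, N0 = 1e6,
    chi0 = 0, f_d = 0, Phi = 1))
}

# reduced sampler settings for module-level tests (fast, converged enough
# for the qualitative properties being checked)
fast_fit_config <- function() {
  list(n_steps = 400, n_walkers = 18, burnin = 200, thin = 4,
       optim_maxit = 300)
}

# the sampler settings used for the study-sized fits in the acceptance
# checks
accept_fit_config <- function() {
  list(n_steps = 800, n_walkers = 20, burnin = 400, thin = 6,
       optim_maxit = 500)
}

tight_influx_prior <- function(params, sdlog = 0.15) {
  list(phi_rate = list(dist = "lognormal",
                       meanlog = log(params$Phi / params$N0),
                       sdlog = sdlog))
}
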