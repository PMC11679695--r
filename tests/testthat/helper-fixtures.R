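# Shared fixtures. Expensive trajectories are built once per test run
# and memoised in this environment.

.fx <- new.env()

fx_speciation_sbf <- function() {
  if (is.null(.fx$sp_sbf)) .fx$sp_sbf <- speciate(sbf_medium())
  .fx$sp_sbf
}

fx_speciation_dmem_fbs <- function() {
  if (is.null(.fx$sp_dmem)) .fx$sp_dmem <- speciate(dmem_fbs_medium())
  .fx$sp_dmem
}

# noise-free Model I trajectory, quarter-day sampling
fx_trajectory_model_I <- function() {
  if (is.null(.fx$traj1))
    .fx$traj1 <- simulate_trajectory(
      material_sample(), kinetic_parameters(), protocol_model_I(),
      sbf_medium(), times_days = seq(0, 14, by = 0.25))
  .fx$traj1
}

# Model II trajectory with the published fitted constants
fx_trajectory_model_II <- function() {
  if (is.null(.fx$traj2))
    .fx$traj2 <- simulate_trajectory(
      material_sample(), kinetic_parameters(beta_kink = 0.656),
      protocol_model_II(), dmem_fbs_medium(), times_days = 0:14)
  .fx$traj2
}

# noise-free synthetic observables at the ground-truth parameters
fx_noise_free_obs <- function() {
  if (is.null(.fx$obs0)) {
    spec <- generator_spec(seed = 1)
    spec$noise_sd[] <- 0
    .fx$obs0 <- generate_observables(spec)
  }
  .fx$obs0
}

truth_pars <- c(pk1 = 6.87, pk2 = 7.04, delta = 25.01)
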