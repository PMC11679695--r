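# Synthetic observable generator: noise-free forward trajectories from
# known ground-truth parameters, sampled daily at the pre-exchange
# instants, with independent Gaussian measurement noise per observable
# kind. Emulates the daily gravimetric/potentiometric sampling design
# of a 14-day dissolution experiment so every analysis stage is testable
# without experimental data.

.default_noise_sd <- c(mass_loss = 0.001, free_ca = 0.05, pH = 0.05,
                       omega_ocp = 0.02, surface_area = 0.3)

#' Synthetic-data generator specification
#'
#' @param truth Ground-truth [kinetic_parameters()].
#' @param sample [material_sample()].
#' @param prot [protocol()].
#' @param med [medium()].
#' @param noise_sd Named vector of per-kind measurement SDs. Defaults:
#'   mass 0.001 g, free Ca 0.05 mM, pH 0.05, omega_OCP 0.02,
#'   surface area 0.3 m^2 (the order of the reported instrument
#'   scatter).
#' @param times_days Sampling times (default daily, 0-14).
#' @param seed Integer RNG seed.
#' @return An object of class `cap_generator`.
#' @export
generator_spec <- function(truth = kinetic_parameters(),
                           sample = material_sample(),
                           prot = protocol_model_I(),
                           med = sbf_medium(),
                           noise_sd = .default_noise_sd,
                           times_days = 0:14, seed = 1) {
  stopifnot(all(noise_sd >= 0),
            all(names(noise_sd) %in% .obs_kinds),
            all(times_days >= 0),
            all(times_days <= prot$duration_days))
  sd_full <- .default_noise_sd
  sd_full[names(noise_sd)] <- noise_sd
  structure(list(truth = truth, sample = sample, prot = prot, med = med,
                 noise_sd = sd_full, times_days = sort(unique(times_days)),
                 seed = as.integer(seed)),
            class = "cap_generator")
}

#' Generate synthetic observable series
#'
#' Integrates the forward model at the ground-truth parameters, samples
#' it at the specification's times, and adds independent Gaussian noise
#' per observable kind. The OCP mass fraction is clipped to `[0, 1]`;
#' masses and areas to non-negative values. The mass series carries
#' `role = "fit"`, all others `role = "verify"` (the gravimetry-anchored
#' split of the calibration). Deterministic for a given seed.
#'
#' @param spec A [generator_spec()].
#' @return A `cap_observables` data frame covering all five kinds.
#' @export
generate_observables <- function(spec) {
  stopifnot(inherits(spec, "cap_generator"))
  traj <- simulate_trajectory(spec$sample, spec$truth, spec$prot, spec$med,
                              times_days = spec$times_days)
  set.seed(spec$seed)
  out <- lapply(.obs_kinds, function(k) {
    clean <- .obs_predict(traj, k)
    noisy <- clean + stats::rnorm(length(clean), 0, spec$noise_sd[[k]])
    noisy <- switch(k,
      omega_ocp = pmin(pmax(noisy, 0), 1),
      mass_loss = , surface_area = pmax(noisy, 0),
      free_ca = pmax(noisy, 0),
      noisy)
    observable_series(k, traj$t_days, noisy,
                      sd = max(spec$noise_sd[[k]], .Machine$double.eps),
                      role = if (k == "mass_loss") "fit" else "verify")
  })
  out <- do.call(rbind, out)
  class(out) <- c("cap_observables", "data.frame")
  out
}

#' Write a self-contained fixture bundle
#'
#' Writes medium, protocol and ground-truth parameter JSON files plus a
#' generated observables CSV for one of the two packaged scenarios:
#' `"model_I_sbf"` (static SBF, beta_kink = 1, Tris pH) or
#' `"model_II_dmem_fbs"` (DMEM + 3.2 g/L albumin, beta_kink = 0.656,
#' daily 50 % exchange, fixed pH 7.4).
#'
#' @param scenario Scenario name.
#' @param dir Output directory (created if needed).
#' @param seed RNG seed for the observable noise.
#' @return Invisibly, the named vector of file paths written.
#' @export
make_fixture_bundle <- function(scenario = c("model_I_sbf",
                                             "model_II_dmem_fbs"),
                                dir, seed = 1) {
  scenario <- match.arg(scenario)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spec <- scenario_generator(scenario, seed = seed)
  paths <- c(medium = file.path(dir, "medium.json"),
             protocol = file.path(dir, "protocol.json"),
             truth = file.path(dir, "truth.json"),
             observables = file.path(dir, "observables.csv"))
  write_medium(spec$med, paths[["medium"]])
  write_protocol(spec$prot, paths[["protocol"]])
  jsonlite::write_json(
    list(pk1 = spec$truth$pk1, pk2 = spec$truth$pk2,
         n1 = spec$truth$n1, n2 = spec$truth$n2,
         delta = spec$truth$delta, beta_kink = spec$truth$beta_kink,
         seed = spec$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  write_observables(generate_observables(spec), paths[["observables"]])
  invisible(paths)
}

#' Generator specification for a packaged scenario
#'
#' @inheritParams make_fixture_bundle
#' @param seed RNG seed.
#' @return A [generator_spec()].
#' @export
scenario_generator <- function(scenario = c("model_I_sbf",
                                            "model_II_dmem_fbs"),
                               seed = 1) {
  scenario <- match.arg(scenario)
  if (scenario == "model_I_sbf") {
    generator_spec(truth = kinetic_parameters(beta_kink = 1),
                   prot = protocol_model_I(), med = sbf_medium(),
                   seed = seed)
  } else {
    generator_spec(truth = kinetic_parameters(beta_kink = 0.656),
                   prot = protocol_model_II(), med = dmem_fbs_medium(),
                   seed = seed)
  }
}
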