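test_that("objective: zero at perfect prediction, simple arithmetic", {
  obs <- fx_noise_free_obs()
  s <- material_sample(); pr <- protocol_model_I(); m <- sbf_medium()
  # at the generating parameters only integrator noise remains
  unit_sd <- obs
  unit_sd$sd <- 1
  phi0 <- fit_objective(unname(truth_pars), unit_sd, s, pr, m)
  expect_lt(phi0, 1e-10)
  # single point, sd = 1, residual 2 -> phi = 4
  traj <- simulate_trajectory(s, kinetic_parameters(), pr, m,
                              times_days = 7)
  one <- observable_series("mass_loss", 7,
                           traj$m_dcpd_g + traj$m_ocp_g + 2,
                           sd = 1, role = "fit")
  expect_equal(fit_objective(unname(truth_pars), one, s, pr, m), 4,
               tolerance = 1e-6)
})

test_that("objective agrees with an independent summation to 1e-12", {
  spec <- generator_spec(seed = 5)
  obs <- generate_observables(spec)
  s <- material_sample(); pr <- protocol_model_I(); m <- sbf_medium()
  phi <- fit_objective(c(6.9, 7.1, 30), obs, s, pr, m)
  # oracle: explicit loop over fit rows against a fresh simulation
  fit_rows <- obs[obs$role == "fit", ]
  traj <- simulate_trajectory(s, kinetic_parameters(6.9, 7.1, delta = 30),
                              pr, m, times_days = sort(unique(fit_rows$t_days)),
                              rtol = 1e-8, atol = 1e-10)
  acc <- 0
  for (i in seq_len(nrow(fit_rows))) {
    pred <- traj$m_dcpd_g[traj$t_days == fit_rows$t_days[i]] +
      traj$m_ocp_g[traj$t_days == fit_rows$t_days[i]]
    acc <- acc + (fit_rows$value[i] - pred)^2 / fit_rows$sd[i]^2
  }
  expect_equal(phi, acc, tolerance = 1e-12)
})

test_that("objective is invariant under observation order", {
  obs <- generate_observables(generator_spec(seed = 9))
  s <- material_sample(); pr <- protocol_model_I(); m <- sbf_medium()
  perm <- obs[sample.int(nrow(obs)), ]
  expect_equal(fit_objective(c(7, 7, 40), obs, s, pr, m),
               fit_objective(c(7, 7, 40), perm, s, pr, m))
})

test_that("fitting is deterministic for a fixed seed", {
  obs <- generate_observables(generator_spec(seed = 3))
  s <- material_sample(); pr <- protocol_model_I(); m <- sbf_medium()
  sched <- annealing_schedule(steps = 15)
  f1 <- fit_kinetics(obs, s, pr, m, seed = 99, schedule = sched)
  f2 <- fit_kinetics(obs, s, pr, m, seed = 99, schedule = sched)
  expect_identical(f1[c("pk1", "pk2", "delta", "objective_value",
                        "n_evaluations")],
                   f2[c("pk1", "pk2", "delta", "objective_value",
                        "n_evaluations")])
})

test_that("bounds collapsed to a point return that point", {
  obs <- fx_noise_free_obs()
  s <- material_sample(); pr <- protocol_model_I(); m <- sbf_medium()
  pt <- c(7.0, 7.2, 30)
  f <- fit_kinetics(obs, s, pr, m, initial = pt, lower = pt, upper = pt,
                    seed = 1, schedule = annealing_schedule(steps = 5))
  expect_equal(c(f$pk1, f$pk2, f$delta), pt)
  expect_equal(f$objective_value,
               fit_objective(pt, obs, s, pr, m), tolerance = 1e-9)
})

test_that("the polish never worsens the incumbent objective", {
  obs <- generate_observables(generator_spec(seed = 21))
  s <- material_sample(); pr <- protocol_model_I(); m <- sbf_medium()
  start <- c(6.9, 7.1, 30)
  # with zero annealing steps the incumbent is the start point, so the
  # reported objective is the polish result and must not exceed it
  f <- fit_kinetics(obs, s, pr, m, initial = start, seed = 7,
                    schedule = annealing_schedule(steps = 0))
  expect_lte(f$objective_value,
             fit_objective(start, obs, s, pr, m) + 1e-9)
})

test_that("verification reports per-series statistics without refitting", {
  obs <- fx_noise_free_obs()
  s <- material_sample(); pr <- protocol_model_I(); m <- sbf_medium()
  fit <- structure(list(pk1 = 6.87, pk2 = 7.04, delta = 25.01,
                        beta_kink = 1, converged = TRUE), class = "cap_fit")
  # on noise-free data at the generating parameters: rmse ~ 0
  rep <- verify_fit(fit, obs[obs$role == "verify", ], s, pr, m)
  expect_setequal(rep$kind, c("free_ca", "pH", "omega_ocp", "surface_area"))
  expect_true(all(rep$rmse < 1e-6))
  # empty verification set -> empty report
  empty <- verify_fit(fit, obs[0, ], s, pr, m)
  expect_equal(nrow(empty), 0L)
  # with noise at a known SD the normalized residual SD is near 1
  spec <- generator_spec(seed = 31,
                         times_days = seq(0.25, 14, length.out = 50))
  noisy <- generate_observables(spec)
  ca <- noisy[noisy$kind == "free_ca", ]
  rep2 <- verify_fit(fit, ca, s, pr, m)
  expect_gt(rep2$norm_resid_sd, 0.7)
  expect_lt(rep2$norm_resid_sd, 1.3)
})
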