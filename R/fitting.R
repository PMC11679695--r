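# Kinetic parameter estimation: weighted least squares on observable
# time series, globalised by simulated annealing over (pk1, pk2, delta)
# with a local polish, as in the gravimetry-anchored calibration of the
# model (mass-change series fitted; pCa, omega_OCP and surface area held
# out for verification).

.obs_kinds <- c("mass_loss", "free_ca", "pH", "omega_ocp", "surface_area")

#' Observable time series
#'
#' A tidy table of timestamped measurements with per-point standard
#' deviations and a fit/verify role, one row per observation.
#'
#' @param kind One of `"mass_loss"` (total sample mass, g), `"free_ca"`
#'   (mM), `"pH"`, `"omega_ocp"` (OCP mass fraction), `"surface_area"`
#'   (total area, m^2).
#' @param times Observation times in days (strictly increasing).
#' @param values Measured values in the kind's units.
#' @param sd Per-point standard deviation (same units); must be > 0 for
#'   fit-role series.
#' @param role `"fit"` or `"verify"`.
#' @return A data frame of class `cap_observables` with columns `kind`,
#'   `t_days`, `value`, `sd`, `role`. Multiple series are combined with
#'   `rbind`.
#' @export
observable_series <- function(kind, times, values, sd, role = "verify") {
  kind <- match.arg(kind, .obs_kinds)
  role <- match.arg(role, c("fit", "verify"))
  stopifnot(length(times) == length(values))
  if (is.unsorted(times, strictly = TRUE))
    stop("observation times must be strictly increasing", call. = FALSE)
  sd <- rep_len(sd, length(times))
  if (role == "fit" && any(sd <= 0))
    stop("fit-role series need sd > 0 for every point", call. = FALSE)
  structure(data.frame(kind = kind, t_days = times, value = values,
                       sd = sd, role = role, stringsAsFactors = FALSE),
            class = c("cap_observables", "data.frame"))
}

# trajectory column backing each observable kind
.obs_predict <- function(traj, kind) {
  switch(kind,
    mass_loss    = traj$m_dcpd_g + traj$m_ocp_g,
    free_ca      = traj$ca_free_mM,
    pH           = traj$pH,
    omega_ocp    = traj$omega_ocp,
    surface_area = traj$s1_m2 + traj$s2_m2,
    stop("unknown observable kind: ", kind, call. = FALSE))
}

# forward model sampled at the union of observation times
.predict_observables <- function(obs, sample, prot, med, params, rtol) {
  tt <- sort(unique(obs$t_days))
  traj <- simulate_trajectory(sample, params, prot, med, times_days = tt,
                              rtol = rtol, atol = rtol * 1e-2)
  idx <- match(obs$t_days, traj$t_days)
  vapply(seq_len(nrow(obs)),
         function(i) .obs_predict(traj[idx[i], , drop = FALSE], obs$kind[i]),
         numeric(1))
}

#' Weighted least-squares objective
#'
#' `phi = sum_k W_k (obs_k - pred_k)^2` over all fit-role observations,
#' with inverse-variance weights `W_k = 1/sd_k^2` (or `1/sd_k` with
#' `weighting = "inv_sd"`). Predictions come from a forward integration
#' at the observation times; an integration failure yields `Inf` (with
#' the cause attached as an attribute), which keeps the annealing loop
#' safe.
#'
#' @param par Numeric vector `c(pk1, pk2, delta)`.
#' @param series A `cap_observables` table (only `role == "fit"` rows
#'   enter the objective).
#' @param sample,prot,med Model context as for [simulate_trajectory()].
#' @param n1,n2,beta_kink Fixed kinetic settings (orders are not
#'   fitted).
#' @param weighting `"inv_var"` or `"inv_sd"`.
#' @param rtol Integrator tolerance used during fitting.
#' @return The scalar objective value.
#' @export
fit_objective <- function(par, series, sample, prot, med,
                          n1 = 1, n2 = 4, beta_kink = 1,
                          weighting = c("inv_var", "inv_sd"),
                          rtol = 1e-8) {
  weighting <- match.arg(weighting)
  fit_rows <- series[series$role == "fit", , drop = FALSE]
  if (!nrow(fit_rows)) stop("no fit-role observations", call. = FALSE)
  params <- kinetic_parameters(pk1 = par[1], pk2 = par[2], n1 = n1,
                               n2 = n2, delta = par[3],
                               beta_kink = beta_kink)
  pred <- tryCatch(
    .predict_observables(fit_rows, sample, prot, med, params, rtol),
    error = function(e) e)
  if (inherits(pred, "error"))
    return(structure(Inf, cause = conditionMessage(pred)))
  w <- if (weighting == "inv_var") 1 / fit_rows$sd^2 else 1 / fit_rows$sd
  sum(w * (fit_rows$value - pred)^2)
}

#' Annealing schedule
#'
#' Geometric cooling with Gaussian proposals in `(pk1, pk2, log delta)`.
#'
#' @param T0 Initial temperature (scaled by the starting objective).
#' @param ratio Cooling ratio per step.
#' @param steps Number of annealing steps.
#' @param step_sd Proposal standard deviations in
#'   `(pk1, pk2, log delta)`.
#' @return A list used by [fit_kinetics()].
#' @export
annealing_schedule <- function(T0 = 1.0, ratio = 0.95, steps = 200,
                               step_sd = c(0.25, 0.25, 0.25)) {
  stopifnot(T0 > 0, ratio > 0, ratio < 1, steps >= 0)
  list(T0 = T0, ratio = ratio, steps = steps, step_sd = step_sd)
}

#' Fit kinetic parameters to observable series
#'
#' Simulated-annealing global search over `(pk1, pk2, delta)` within
#' bounds, followed by a bounded local least-squares polish
#' (Levenberg-Marquardt on the weighted residual vector,
#' [minpack.lm::nls.lm()]) from the annealing incumbent; the polished
#' point is only accepted if it does not increase the objective.
#' Effective reaction orders are held fixed (`n1 = 1`, `n2 = 4`).
#' Deterministic for a given seed.
#'
#' @param series `cap_observables` with at least one fit-role row.
#' @param sample,prot,med Model context.
#' @param initial Starting values `c(pk1, pk2, delta)`.
#' @param lower,upper Bounds (defaults pk in `[4, 10]`, delta in
#'   `[0, 100]`).
#' @param seed RNG seed for the annealing stage.
#' @param schedule [annealing_schedule()].
#' @param beta_kink Fixed protein-inhibition prefactor of the scenario.
#' @param weighting,rtol Passed to [fit_objective()].
#' @param polish_control Control list for the Levenberg-Marquardt
#'   polish (see [minpack.lm::nls.lm.control()]).
#' @return An object of class `cap_fit` with elements `pk1`, `pk2`,
#'   `delta`, `objective_value`, `n_evaluations`, `seed`, `converged`.
#' @export
fit_kinetics <- function(series, sample, prot, med,
                         initial = c(pk1 = 7, pk2 = 7, delta = 50),
                         lower = c(4, 4, 0), upper = c(10, 10, 100),
                         seed = 1, schedule = annealing_schedule(),
                         beta_kink = 1,
                         weighting = c("inv_var", "inv_sd"),
                         rtol = 1e-8,
                         polish_control = list(maxiter = 100,
                                               ftol = 1e-15,
                                               ptol = 1e-12)) {
  weighting <- match.arg(weighting)
  if (!nrow(series[series$role == "fit", , drop = FALSE]))
    stop("fit_kinetics(): no fit-role observations", call. = FALSE)
  stopifnot(length(initial) == 3, all(is.finite(lower)), all(is.finite(upper)),
            all(lower <= upper))
  initial <- pmin(pmax(unname(initial), lower), upper)

  n_eval <- 0L
  phi <- function(p) {
    n_eval <<- n_eval + 1L
    fit_objective(p, series, sample, prot, med, beta_kink = beta_kink,
                  weighting = weighting, rtol = rtol)
  }

  # --- simulated annealing in (pk1, pk2, log delta) ------------------
  to_search <- function(p) c(p[1], p[2], log(max(p[3], 1e-6)))
  from_search <- function(q) {
    p <- c(q[1], q[2], exp(q[3]))
    pmin(pmax(p, lower), upper)
  }
  set.seed(seed)
  cur <- initial; cur_phi <- phi(cur)
  best <- cur; best_phi <- cur_phi
  scale <- max(cur_phi, .Machine$double.eps)
  Temp <- schedule$T0
  for (s in seq_len(schedule$steps)) {
    q <- to_search(cur) + stats::rnorm(3, 0, schedule$step_sd)
    cand <- from_search(q)
    cand_phi <- phi(cand)
    if (is.finite(cand_phi) &&
        (cand_phi < cur_phi ||
         stats::runif(1) < exp(-(cand_phi - cur_phi) / (Temp * scale)))) {
      cur <- cand; cur_phi <- cand_phi
      if (cur_phi < best_phi) { best <- cur; best_phi <- cur_phi }
    }
    Temp <- Temp * schedule$ratio
  }

  # --- local polish (never accepted if it worsens the incumbent) -----
  fit_rows <- series[series$role == "fit", , drop = FALSE]
  sw <- if (weighting == "inv_var") 1 / fit_rows$sd else 1 / sqrt(fit_rows$sd)
  resid_fun <- function(p) {
    n_eval <<- n_eval + 1L
    params <- kinetic_parameters(pk1 = p[1], pk2 = p[2],
                                 delta = max(p[3], 0),
                                 beta_kink = beta_kink)
    pred <- tryCatch(
      .predict_observables(fit_rows, sample, prot, med, params, rtol),
      error = function(e) NULL)
    if (is.null(pred)) return(rep(sqrt(.Machine$double.xmax / length(sw)),
                                  length(sw)))
    sw * (fit_rows$value - pred)
  }
  converged <- FALSE
  polish <- tryCatch(
    minpack.lm::nls.lm(par = best, lower = lower, upper = upper,
                       fn = resid_fun,
                       control = do.call(minpack.lm::nls.lm.control,
                                         polish_control)),
    error = function(e) NULL)
  if (!is.null(polish)) {
    cand <- pmin(pmax(unname(polish$par), lower), upper)
    cand_phi <- phi(cand)
    if (is.finite(cand_phi) && cand_phi <= best_phi) {
      best <- cand
      best_phi <- cand_phi
      converged <- TRUE
    }
  }

  structure(list(pk1 = best[1], pk2 = best[2], delta = best[3],
                 objective_value = best_phi, n_evaluations = n_eval,
                 seed = seed, converged = converged,
                 beta_kink = beta_kink, weighting = weighting),
            class = "cap_fit")
}

#' @export
print.cap_fit <- function(x, ...) {
  cat("Kinetic fit: pk1 =", format(round(x$pk1, 4)),
      " pk2 =", format(round(x$pk2, 4)),
      " delta =", format(round(x$delta, 3)), "m2/g\n")
  cat("objective =", format(x$objective_value),
      " evaluations =", x$n_evaluations,
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Verify a fit against held-out series
#'
#' Runs a fresh forward simulation at the fitted parameters and reports
#' per-series residual statistics for the verify-role observations; no
#' refitting is performed.
#'
#' @param fit A `cap_fit`.
#' @param verify_series `cap_observables` (rows with any role are
#'   compared as given).
#' @param sample,prot,med Model context.
#' @param rtol Integrator tolerance.
#' @return A data frame with one row per kind: `n`, `rmse`,
#'   `norm_resid_mean`, `norm_resid_sd` (residuals scaled by the stated
#'   sd).
#' @export
verify_fit <- function(fit, verify_series, sample, prot, med,
                       rtol = 1e-8) {
  stopifnot(inherits(fit, "cap_fit"))
  if (!nrow(verify_series))
    return(data.frame(kind = character(), n = integer(), rmse = numeric(),
                      norm_resid_mean = numeric(), norm_resid_sd = numeric()))
  params <- kinetic_parameters(pk1 = fit$pk1, pk2 = fit$pk2,
                               delta = fit$delta,
                               beta_kink = fit$beta_kink)
  pred <- .predict_observables(verify_series, sample, prot, med, params,
                               rtol)
  res <- verify_series$value - pred
  nres <- res / verify_series$sd
  agg <- split(seq_len(nrow(verify_series)), verify_series$kind)
  out <- do.call(rbind, lapply(names(agg), function(k) {
    i <- agg[[k]]
    data.frame(kind = k, n = length(i),
               rmse = sqrt(mean(res[i]^2)),
               norm_resid_mean = mean(nres[i]),
               norm_resid_sd = stats::sd(nres[i]))
  }))
  rownames(out) <- NULL
  out
}
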