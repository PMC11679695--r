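# Coupled DCPD-dissolution / OCP-crystallization kinetics against an
# evolving solution: semi-empirical rate laws, linear surface-area
# feedback, stoichiometric bookkeeping, Tris or fixed-pH handling and
# periodic medium exchange. Integration is quasi-static: solution
# equilibria are fast relative to the interfacial kinetics, so the
# speciation is re-solved at every right-hand-side evaluation.

#' Material sample descriptor
#'
#' @param initial_mass Sample mass in g (default: the tablet fixture,
#'   0.6477 g).
#' @param specific_surface Specific surface area in m^2/g (BET; default
#'   5.3).
#' @param dissolving,precipitating [phase()] objects for the dissolving
#'   and precipitating phases (defaults DCPD and OCP).
#' @return An object of class `cap_sample`.
#' @export
material_sample <- function(initial_mass = 0.6477, specific_surface = 5.3,
                            dissolving = dcpd_phase(),
                            precipitating = ocp_phase()) {
  stopifnot(initial_mass >= 0, specific_surface > 0,
            inherits(dissolving, "cap_phase"),
            inherits(precipitating, "cap_phase"))
  structure(list(initial_mass = initial_mass,
                 specific_surface = specific_surface,
                 dissolving = dissolving, precipitating = precipitating),
            class = "cap_sample")
}

#' Kinetic parameters of the rate model
#'
#' Semi-empirical rates `J_DCPD = k1 s1 sigma_DCPD^n1` (dissolution,
#' g/s) and `J_OCP = beta_kink k2 s2 |sigma_OCP|^n2` (growth, g/s), with
#' the linear surface-area law coefficient `delta` (m^2 of area
#' exchanged per gram of OCP formed). Rate constants are specified as
#' `pk = -log10(k)`, the scale on which they are reported and fitted;
#' the optimized values are pk1 = 6.87, pk2 = 7.04, delta = 25.01.
#'
#' @param pk1,pk2 Dissolution and growth rate constants as -log10 of
#'   k (g s^-1 m^-2).
#' @param n1,n2 Integer effective reaction orders (1 and 4).
#' @param delta Surface-area coupling, m^2/g.
#' @param beta_kink Protein-inhibition prefactor in (0, 1]; 1 without
#'   protein, ~0.656 for serum albumin (see [langmuir_beta()]).
#' @return An object of class `cap_params`.
#' @export
kinetic_parameters <- function(pk1 = 6.87, pk2 = 7.04, n1 = 1, n2 = 4,
                               delta = 25.01, beta_kink = 1) {
  stopifnot(n1 >= 1, n2 >= 1, n1 == round(n1), n2 == round(n2),
            delta >= 0, beta_kink > 0, beta_kink <= 1)
  structure(list(pk1 = pk1, pk2 = pk2, k1 = 10^(-pk1), k2 = 10^(-pk2),
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 delta = delta, beta_kink = beta_kink),
            class = "cap_params")
}

#' Experimental protocol
#'
#' @param solution_to_sample_mass_ratio Solution mass per sample mass
#'   (default 100, i.e. 1/100 sample/solution).
#' @param solution_density g/mL (default 1.0).
#' @param duration_days Length of the experiment.
#' @param exchange_fraction Fraction of the solution replaced by fresh
#'   medium at each exchange event (0 = static, 0.5 = daily half-volume
#'   replacement).
#' @param exchange_period_days Interval between exchange events.
#' @param pH_mode `"tris_dynamic"` (pH follows the Tris titration of the
#'   protons released by OCP growth) or `"fixed"` (carbonate-buffered
#'   constant pH).
#' @param fixed_pH pH used in `"fixed"` mode.
#' @param surface_area_mode `"both_evolve"` (s1 shrinks and s2 grows by
#'   `delta * m_OCP`; the static SBF protocol) or `"s2_constant"` (s1
#'   still shrinks but the OCP growth area is held at the sample's
#'   initial total area, matching the unchanged BET area of the
#'   serum-medium experiments).
#' @param s2_seed_fraction Initial OCP area as a fraction of the initial
#'   DCPD area in `"both_evolve"` mode (a seed so growth can start).
#' @param tris_pKa Tris pKa at 37 degC (default 7.72).
#' @param solution_volume_mL Override for the solution volume; by
#'   default it follows from the mass ratio and density.
#' @return An object of class `cap_protocol`.
#' @export
protocol <- function(solution_to_sample_mass_ratio = 100,
                     solution_density = 1.0, duration_days = 14,
                     exchange_fraction = 0, exchange_period_days = 1,
                     pH_mode = c("tris_dynamic", "fixed"), fixed_pH = 7.4,
                     surface_area_mode = c("both_evolve", "s2_constant"),
                     s2_seed_fraction = 1e-3, tris_pKa = 7.72,
                     solution_volume_mL = NULL) {
  pH_mode <- match.arg(pH_mode)
  surface_area_mode <- match.arg(surface_area_mode)
  stopifnot(solution_to_sample_mass_ratio > 0, solution_density > 0,
            duration_days >= 0, exchange_fraction >= 0,
            exchange_fraction <= 1, exchange_period_days > 0,
            s2_seed_fraction >= 0)
  structure(list(
    solution_to_sample_mass_ratio = solution_to_sample_mass_ratio,
    solution_density = solution_density, duration_days = duration_days,
    exchange_fraction = exchange_fraction,
    exchange_period_days = exchange_period_days, pH_mode = pH_mode,
    fixed_pH = fixed_pH, surface_area_mode = surface_area_mode,
    s2_seed_fraction = s2_seed_fraction, tris_pKa = tris_pKa,
    solution_volume_mL = solution_volume_mL
  ), class = "cap_protocol")
}

#' Static SBF protocol (Model I conditions)
#'
#' 14 days in Tris-buffered SBF without medium exchange; both surface
#' areas evolve linearly with the OCP mass.
#' @export
protocol_model_I <- function() {
  protocol(exchange_fraction = 0, pH_mode = "tris_dynamic",
           surface_area_mode = "both_evolve")
}

#' Perfusion DMEM+FBS protocol (Model II conditions)
#'
#' 14 days with daily half-volume replacement by fresh medium, pH held
#' at 7.4 by the carbonate buffer, OCP growth area constant.
#' @export
protocol_model_II <- function() {
  protocol(exchange_fraction = 0.5, exchange_period_days = 1,
           pH_mode = "fixed", fixed_pH = 7.4,
           surface_area_mode = "s2_constant")
}

#' DCPD dissolution rate
#'
#' `J = k1 * s1 * sigma^n1` (g/s of solid lost) when the solution is
#' undersaturated (`sigma_dcpd > 0`), zero otherwise.
#'
#' @param sigma_dcpd Relative undersaturation `1 - S_DCPD`.
#' @param s1 DCPD-solution contact area, m^2.
#' @param params [kinetic_parameters()].
#' @return Mass-loss rate in g/s.
#' @export
rate_dcpd <- function(sigma_dcpd, s1, params) {
  stopifnot(s1 >= 0)
  ifelse(sigma_dcpd > 0, params$k1 * s1 * sigma_dcpd^params$n1, 0)
}

#' OCP crystallization rate
#'
#' `J = beta_kink * k2 * s2 * |sigma|^n2` (g/s of solid gained) when the
#' solution is supersaturated (`S_OCP > 1`, i.e. `sigma_ocp < 0`), zero
#' otherwise.
#'
#' @param sigma_ocp Relative undersaturation `1 - S_OCP` (negative when
#'   growing).
#' @param s2 OCP growth area, m^2.
#' @param params [kinetic_parameters()].
#' @return Mass-gain rate in g/s.
#' @export
rate_ocp <- function(sigma_ocp, s2, params) {
  stopifnot(s2 >= 0)
  ifelse(sigma_ocp < 0,
         params$beta_kink * params$k2 * s2 * abs(sigma_ocp)^params$n2, 0)
}

#' Linear surface-area evolution
#'
#' `s1 = max(0, s1_0 - m_ocp * delta)`; `s2 = s2_0 + m_ocp * delta` when
#' both areas evolve, or `s2 = s2_0` in `s2_constant` mode.
#'
#' @param m_ocp Mass of crystallized OCP, g.
#' @param s1_0,s2_0 Initial areas, m^2.
#' @param params [kinetic_parameters()] (supplies `delta`).
#' @param mode `"both_evolve"` or `"s2_constant"`.
#' @return Named vector `c(s1 = , s2 = )`.
#' @export
update_surface_areas <- function(m_ocp, s1_0, s2_0, params,
                                 mode = c("both_evolve", "s2_constant")) {
  mode <- match.arg(mode)
  stopifnot(m_ocp >= 0)
  s1 <- max(0, s1_0 - m_ocp * params$delta)
  s2 <- if (mode == "both_evolve") s2_0 + m_ocp * params$delta else s2_0
  c(s1 = s1, s2 = s2)
}

#' Protein-inhibition prefactor from a Langmuir constant
#'
#' Albumin adsorbing onto growth sites raises the effective barrier by
#' the adsorption free energy `dG_ad = -RT ln(K)`, reducing the growth
#' rate by `beta_kink = exp(dG_ad / RT) = 1/K` on the constant's own
#' concentration scale. For serum albumin on OCP, K = 1.52 gives
#' beta ~ 0.658 (reported as ~0.656).
#'
#' @param K Langmuir adsorption constant (first-type isotherm).
#' @return `beta_kink` in (0, 1] for K >= 1.
#' @export
langmuir_beta <- function(K) {
  if (any(K <= 0)) stop("Langmuir constant must be > 0", call. = FALSE)
  1 / K
}

#' Mix the solution with fresh medium
#'
#' Every solution total becomes
#' `(1 - fraction) * current + fraction * fresh`; solid masses and
#' surface areas are unaffected by an exchange event.
#'
#' @param totals Named numeric vector of current solution totals (mM).
#' @param fresh_totals Fresh-medium totals (same names, mM).
#' @param fraction Replaced volume fraction in `[0, 1]`.
#' @return Mixed totals (mM).
#' @export
apply_medium_exchange <- function(totals, fresh_totals, fraction) {
  if (fraction < 0 || fraction > 1)
    stop("exchange fraction must lie in [0, 1]", call. = FALSE)
  (1 - fraction) * totals + fraction * fresh_totals[names(totals)]
}

#' Stoichiometric bookkeeping of a dissolution/precipitation step
#'
#' Dissolving `dm_dcpd` grams of DCPD adds `dm/172.09` mol each of total
#' Ca and total P to the solution; precipitating `dm_ocp` grams of OCP
#' removes `8 dm/982.6` mol Ca and `6 dm/982.6` mol P and releases
#' `4 dm/982.6` mol H+ into the proton ledger
#' (8 Ca2+ + 6 HPO4 2- + 5 H2O -> Ca8(HPO4)2(PO4)4.5H2O + 4 H+).
#'
#' @param dm_dcpd_g Mass of DCPD dissolved in the step (g, >= 0).
#' @param dm_ocp_g Mass of OCP precipitated in the step (g, >= 0).
#' @param volume_L Solution volume.
#' @param dissolving,precipitating The two [phase()]s (for molar masses).
#' @return List with `dCa_mM`, `dP_mM` (solution total increments) and
#'   `dH_mol` (protons released).
#' @export
step_stoichiometry <- function(dm_dcpd_g, dm_ocp_g, volume_L,
                               dissolving = dcpd_phase(),
                               precipitating = ocp_phase()) {
  stopifnot(dm_dcpd_g >= 0, dm_ocp_g >= 0, volume_L > 0)
  n_d <- dm_dcpd_g / dissolving$molar_mass
  n_o <- dm_ocp_g / precipitating$molar_mass
  list(dCa_mM = (n_d - 8 * n_o) / volume_L * 1000,
       dP_mM  = (n_d - 6 * n_o) / volume_L * 1000,
       dH_mol = 4 * n_o)
}

#' pH from the proton ledger
#'
#' In `"tris_dynamic"` mode the cumulative acid released by OCP growth
#' titrates the Tris/TrisH+ pair and the pH follows
#' Henderson-Hasselbalch; in `"fixed"` mode the buffer pins the pH.
#'
#' @param acid_mol Cumulative protons released (mol).
#' @param buffer List with `mode` (`"tris_dynamic"`/`"fixed"`),
#'   `fixed_pH`, `tris_mM` (total Tris), `pKa`, `pH0` (initial pH, sets
#'   the initial protonation state) and `volume_L`.
#' @return pH.
#' @export
update_pH <- function(acid_mol, buffer) {
  if (identical(buffer$mode, "fixed")) return(buffer$fixed_pH)
  tris_M <- buffer$tris_mM / 1000
  if (tris_M <= 0) stop("tris_dynamic pH mode needs tris_mM > 0", call. = FALSE)
  trisH0 <- tris_M / (1 + 10^(buffer$pH0 - buffer$pKa))
  trisH <- trisH0 + acid_mol / buffer$volume_L
  free <- tris_M - trisH
  if (free <= 0)
    stop("released acid exceeds the Tris buffer capacity", call. = FALSE)
  buffer$pKa + log10(free / trisH)
}

# speciation + saturation of the instantaneous solution state, shared by
# the integrator and the output post-processing. Returns scalars only.
.traj_speciate <- function(CaT, PT, env) {
  I <- (env$I_const + 0.5 * (4 * CaT + env$zP2 * PT)) / 1000
  g1 <- 10^(-env$A * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I))
  g2 <- g1^4; g3 <- g1^9
  H <- env$aH / g1
  core <- .spec_core(CaT / 1000, env$MgT, PT / 1000, env$CT, env$ST, H,
                     env$cst, albM = env$albM, start = env$warm,
                     tol = env$spec_tol, max_iter = 200)
  if (!core$converged)
    stop(sprintf("speciation failed inside trajectory (Ca=%.4g mM, P=%.4g mM)",
                 CaT, PT), call. = FALSE)
  env$warm <- c(core$free[["Ca"]], core$free[["Mg"]])
  gam <- c(1, g1, g2, g3)
  act <- core$free * gam[.species_charge[names(core$free)] + 1]
  act <- c(act, H = unname(env$aH))
  S1 <- exp((sum(env$iap1 * log(act[names(env$iap1)])) - env$lKsp1) / env$n1u)
  S2 <- exp((sum(env$iap2 * log(act[names(env$iap2)])) - env$lKsp2) / env$n2u)
  list(S1 = S1, S2 = S2, free_ca = core$free[["Ca"]] * 1000,
       free = core$free)
}

#' Integrate the dissolution-crystallization trajectory
#'
#' Quasi-static coupling: at every step the solution speciation is
#' re-solved for the current totals and pH, the saturation ratios give
#' the rates, and masses, solution totals, surface areas and the proton
#' ledger advance together. Exchange events are applied instantaneously
#' at multiples of the exchange period, after the state at the event
#' time has been recorded (so sampled values at event times are the
#' pre-exchange "daily measurements").
#'
#' @param sample A [material_sample()].
#' @param params [kinetic_parameters()].
#' @param prot A [protocol()].
#' @param med The (fresh) [medium()].
#' @param times_days Output times in days (default: daily, 0 to
#'   duration).
#' @param reactions Equilibrium table.
#' @param model [activity_model()].
#' @param rtol,atol Integrator tolerances (deSolve::lsoda).
#' @param spec_tol Speciation residual tolerance, mM.
#' @return A data frame of class `cap_trajectory` with columns `t_days`,
#'   `m_dcpd_g`, `m_ocp_g`, `s1_m2`, `s2_m2`, `ca_total_mM`,
#'   `ca_free_mM`, `p_total_mM`, `pH`, `S_dcpd`, `S_ocp`, `sigma_dcpd`,
#'   `sigma_ocp`, `J_dcpd`, `J_ocp`, `omega_ocp`.
#' @export
simulate_trajectory <- function(sample, params, prot, med,
                                times_days = NULL,
                                reactions = default_equilibria(),
                                model = activity_model(),
                                rtol = 1e-10, atol = 1e-12,
                                spec_tol = 1e-10) {
  stopifnot(inherits(sample, "cap_sample"), inherits(params, "cap_params"),
            inherits(prot, "cap_protocol"), inherits(med, "cap_medium"))
  if (is.null(times_days))
    times_days <- seq(0, prot$duration_days, by = 1)
  times_days <- sort(unique(times_days))
  if (any(times_days < 0) || any(times_days > prot$duration_days))
    stop("output times must lie within the protocol duration", call. = FALSE)

  m0 <- sample$initial_mass
  s1_0 <- m0 * sample$specific_surface
  s2_0 <- if (prot$surface_area_mode == "s2_constant") s1_0
          else prot$s2_seed_fraction * s1_0
  V_L <- if (!is.null(prot$solution_volume_mL)) prot$solution_volume_mL / 1000
         else m0 * prot$solution_to_sample_mass_ratio /
              prot$solution_density / 1000
  if (V_L <= 0) V_L <- 1e-6   # degenerate zero-mass sample: rates are zero

  Mw_d <- sample$dissolving$molar_mass
  Mw_o <- sample$precipitating$molar_mass
  pH0 <- if (prot$pH_mode == "fixed") prot$fixed_pH else med$pH
  buffer <- list(mode = prot$pH_mode, fixed_pH = prot$fixed_pH,
                 tris_mM = med$tris_mM, pKa = prot$tris_pKa,
                 pH0 = med$pH, volume_L = V_L)

  # environment shared by rhs and post-processing: constant totals,
  # compiled equilibrium constants, phase IAPs, warm start
  env <- new.env(parent = emptyenv())
  tot <- med$totals
  env$MgT <- tot[["Mg"]] / 1000; env$CT <- tot[["HCO3"]] / 1000
  env$ST <- tot[["SO4"]] / 1000
  env$zP2 <- .component_charges[[med$phosphate_form]]^2
  const_idx <- setdiff(names(tot), c("Ca", med$phosphate_form))
  tris_cat <- if (med$buffer == "tris") med$tris_mM else 0
  env$I_const <- 0.5 * sum(tot[const_idx] *
                           .component_charges[const_idx]^2) + 0.5 * tris_cat
  env$A <- model$A
  env$cst <- .compile_constants(reactions, med$phosphate_form)
  env$albM <- med$albumin_g_per_L / med$albumin_molar_mass
  env$iap1 <- sample$dissolving$iap; env$lKsp1 <- log(sample$dissolving$Ksp)
  env$n1u <- sample$dissolving$n_ion_units
  env$iap2 <- sample$precipitating$iap
  env$lKsp2 <- log(sample$precipitating$Ksp)
  env$n2u <- sample$precipitating$n_ion_units
  env$spec_tol <- spec_tol / 1000
  env$warm <- NULL

  state_pH <- function(acid) {
    if (prot$pH_mode == "fixed") prot$fixed_pH else update_pH(acid, buffer)
  }

  rhs <- function(t, y, p) {
    md <- max(y[1], 0); mo <- max(y[2], 0)
    CaT <- max(y[3], 1e-12); PT <- max(y[4], 1e-12)
    env$aH <- 10^(-state_pH(unname(y[5])))
    sp <- .traj_speciate(CaT, PT, env)
    sa <- update_surface_areas(mo, s1_0, s2_0, params,
                               prot$surface_area_mode)
    s1 <- if (md > 0) sa[["s1"]] else 0
    Jd <- rate_dcpd(1 - sp$S1, s1, params)
    Jo <- rate_ocp(1 - sp$S2, sa[["s2"]], params)
    list(c(-Jd, Jo,
           (Jd / Mw_d - 8 * Jo / Mw_o) / V_L * 1000,
           (Jd / Mw_d - 6 * Jo / Mw_o) / V_L * 1000,
           4 * Jo / Mw_o))
  }

  # segment boundaries: exchange events strictly inside the duration
  ex_times <- if (prot$exchange_fraction > 0 && prot$duration_days > 0)
    seq(prot$exchange_period_days, prot$duration_days,
        by = prot$exchange_period_days) else numeric(0)
  ex_times <- ex_times[ex_times < prot$duration_days |
                       abs(ex_times - prot$duration_days) < 1e-9]
  bounds <- sort(unique(c(0, ex_times, prot$duration_days)))

  y <- c(md = m0, mo = 0, Ca = tot[["Ca"]], P = tot[[med$phosphate_form]],
         acid = 0)
  rows <- list()
  record <- function(t_day, y) {
    rows[[length(rows) + 1L]] <<- c(t = t_day, y)
  }
  if (any(abs(times_days - 0) < 1e-12)) record(0, y)

  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    if (t1 > t0) {
      inner <- times_days[times_days > t0 + 1e-12 & times_days <= t1 + 1e-12]
      tt <- sort(unique(c(t0, inner, t1))) * 86400
      sol <- deSolve::lsoda(y, tt, rhs, parms = NULL,
                            rtol = rtol, atol = atol)
      for (i in seq_along(tt)[-1]) {
        td <- tt[i] / 86400
        if (any(abs(times_days - td) < 1e-9)) record(td, sol[i, -1])
      }
      y <- sol[nrow(sol), -1]
    }
    if (t1 %in% ex_times) {   # apply exchange after recording
      mixed <- apply_medium_exchange(
        c(Ca = y[["Ca"]], P = y[["P"]]),
        c(Ca = tot[["Ca"]], P = tot[[med$phosphate_form]]),
        prot$exchange_fraction)
      y[["Ca"]] <- mixed[["Ca"]]; y[["P"]] <- mixed[["P"]]
      y[["acid"]] <- (1 - prot$exchange_fraction) * y[["acid"]]
    }
  }

  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("t_days", "m_dcpd_g", "m_ocp_g", "ca_total_mM",
                  "p_total_mM", "acid_mol")
  # diagnostic columns from the recorded states
  n <- nrow(out)
  diag <- matrix(NA_real_, n, 10)
  env$warm <- NULL
  for (i in seq_len(n)) {
    pH_i <- state_pH(out$acid_mol[i])
    env$aH <- 10^(-pH_i)
    sp <- .traj_speciate(max(out$ca_total_mM[i], 1e-12),
                         max(out$p_total_mM[i], 1e-12), env)
    sa <- update_surface_areas(max(out$m_ocp_g[i], 0), s1_0, s2_0, params,
                               prot$surface_area_mode)
    s1 <- if (out$m_dcpd_g[i] > 0) sa[["s1"]] else 0
    Jd <- rate_dcpd(1 - sp$S1, s1, params)
    Jo <- rate_ocp(1 - sp$S2, sa[["s2"]], params)
    diag[i, ] <- c(s1, sa[["s2"]], sp$free_ca, pH_i, sp$S1, sp$S2,
                   1 - sp$S1, 1 - sp$S2, Jd, Jo)
  }
  colnames(diag) <- c("s1_m2", "s2_m2", "ca_free_mM", "pH", "S_dcpd",
                      "S_ocp", "sigma_dcpd", "sigma_ocp", "J_dcpd", "J_ocp")
  out <- cbind(out[c("t_days", "m_dcpd_g", "m_ocp_g")],
               diag[, c("s1_m2", "s2_m2"), drop = FALSE],
               out[c("ca_total_mM")],
               ca_free_mM = diag[, "ca_free_mM"],
               out[c("p_total_mM")],
               diag[, c("pH", "S_dcpd", "S_ocp", "sigma_dcpd",
                        "sigma_ocp", "J_dcpd", "J_ocp"), drop = FALSE])
  out$omega_ocp <- ifelse(out$m_dcpd_g + out$m_ocp_g > 0,
                          out$m_ocp_g / (out$m_dcpd_g + out$m_ocp_g), 0)
  attr(out, "sample") <- sample
  attr(out, "params") <- params
  attr(out, "protocol") <- prot
  attr(out, "medium") <- med
  attr(out, "volume_L") <- V_L
  class(out) <- c("cap_trajectory", "data.frame")
  out
}
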