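# Classical nucleation theory (CNT) quantities for OCP and the
# consistency check between the semi-empirical growth law and CNT in
# the high-supersaturation window.
#
# All quantities are computed per nucleus (molecular volume V_cell/Z and
# Boltzmann's kT), which keeps the Boltzmann exponent dimensionless and
# is algebraically identical to the molar form for the critical radius.

.k_B <- 1.380649e-23     # J/K
.N_A <- 6.02214076e23    # 1/mol

#' CNT parameter set for OCP
#'
#' @param gamma_interfacial Crystal-fluid interfacial tension, J/m^2
#'   (OCP-fluid 4.3e-3).
#' @param V_cell Unit-cell volume in m^3 (OCP: 1220 A^3 = 1.22e-27 m^3).
#' @param Z Formula units per cell (2).
#' @param B Kinetic prefactor (scale free; fit or user-set).
#' @param beta_kink Protein-inhibition prefactor.
#' @param f_heterogeneous Foreign-particle factor in `[0, 1]`.
#' @return An object of class `cap_cnt`.
#' @export
cnt_parameters <- function(gamma_interfacial = 4.3e-3, V_cell = 1.22e-27,
                           Z = 2, B = 1, beta_kink = 1,
                           f_heterogeneous = 1) {
  stopifnot(gamma_interfacial > 0, V_cell > 0, Z >= 1,
            f_heterogeneous >= 0, f_heterogeneous <= 1)
  v_mol <- V_cell / Z                 # molecular volume, m^3
  structure(list(gamma = gamma_interfacial, V_cell = V_cell, Z = Z,
                 v_molecular = v_mol, molar_volume = v_mol * .N_A,
                 B = B, beta_kink = beta_kink, f = f_heterogeneous),
            class = "cap_cnt")
}

#' Critical nucleus radius
#'
#' `r_c = 2 v gamma / (kT ln S)` per nucleus, identical to
#' `2 V_m gamma / (RT ln S)` on the molar scale. Defined only for
#' supersaturated solutions (`S > 1`).
#'
#' @param S Supersaturation ratio (> 1).
#' @param T_K Absolute temperature.
#' @param params [cnt_parameters()].
#' @return Critical radius in m.
#' @examples
#' critical_radius(2.4, 310)   # ~1.4e-9 m for OCP
#' @export
critical_radius <- function(S, T_K = 310, params = cnt_parameters()) {
  if (any(S <= 1))
    stop("critical radius undefined for S <= 1 (no nucleation)", call. = FALSE)
  2 * params$v_molecular * params$gamma / (.k_B * T_K * log(S))
}

#' Nucleation barrier
#'
#' `dG* = 16 pi gamma^3 v^2 / (3 (kT ln S)^2)` per nucleus (J), equal to
#' `(4 pi / 3) gamma r_c^2` (the sphere identity).
#'
#' @inheritParams critical_radius
#' @return Barrier height in J per nucleus.
#' @export
nucleation_barrier <- function(S, T_K = 310, params = cnt_parameters()) {
  if (any(S <= 1))
    stop("nucleation barrier undefined for S <= 1", call. = FALSE)
  16 * pi * params$gamma^3 * params$v_molecular^2 /
    (3 * (.k_B * T_K * log(S))^2)
}

#' CNT nucleation rate
#'
#' `J = beta_kink * B * exp(-dG*/kT) * f`. Returns 0 for `S <= 1`
#' (undersaturated solutions do not nucleate).
#'
#' @inheritParams critical_radius
#' @return Nucleation rate on the scale of `B`.
#' @export
nucleation_rate <- function(S, T_K = 310, params = cnt_parameters()) {
  out <- numeric(length(S))
  ok <- S > 1
  if (any(ok))
    out[ok] <- params$beta_kink * params$B * params$f *
      exp(-nucleation_barrier(S[ok], T_K, params) / (.k_B * T_K))
  out
}

#' Foreign-particle factor in the documented limit
#'
#' The heterogeneous-nucleation correction `f(R', m)` depends on the
#' ratio `R'` of the critical radius to the substrate curvature radius
#' and the epitaxy parameter `m`. For micrometre-scale DCPD plates and a
#' nanometre critical radius `R' -> 0`, and the DCPD/OCP lattice
#' mismatch gives `m -> -1`; in that limit `f = 1` (no heterogeneous
#' advantage). Only this limit is implemented; intermediate `(R', m)`
#' raise an error of class `capkin_not_implemented` rather than guessing
#' the general interpolation.
#'
#' @param R_prime Critical radius / substrate curvature radius (>= 0).
#' @param m Epitaxy (contact) parameter in `[-1, 1]`.
#' @param R_prime_max,m_max Bounds of the accepted limit regime.
#' @return 1 in the limit regime.
#' @export
epitaxy_limit_factor <- function(R_prime, m, R_prime_max = 1e-2,
                                 m_max = -0.5) {
  if (R_prime < 0) stop("R' must be >= 0", call. = FALSE)
  if (m < -1 || m > 1) stop("epitaxy parameter m must lie in [-1, 1]",
                            call. = FALSE)
  if (R_prime <= R_prime_max && m <= m_max) return(1)
  stop(structure(class = c("capkin_not_implemented", "error", "condition"),
                 list(message = paste0(
                   "general f(R', m) interpolation not implemented; ",
                   "only the limit R' -> 0, m -> -1 (f = 1) is supported"),
                   call = sys.call(-1))))
}

#' Compare the growth law with CNT on a trajectory
#'
#' Ordinary least squares of the log OCP growth rate on
#' `ln |sigma_OCP|` restricted to a high-supersaturation window,
#' alongside the CNT rate curve evaluated at the same abscissae (the
#' kinetic prefactor B is absorbed into the intercept by matching mean
#' levels, so shapes are compared). By default the growth rate is
#' normalised by the instantaneous OCP area (`J/s2`, g s^-1 m^-2),
#' which isolates the driving-force power law from the autocatalytic
#' area growth; with `normalize_area = FALSE` the raw `J_OCP` is used.
#'
#' @param trajectory A `cap_trajectory`.
#' @param window Numeric interval of S_OCP values defining the window.
#' @param T_K Temperature for the CNT curve.
#' @param params [cnt_parameters()].
#' @param normalize_area Regress the area-specific rate (default TRUE).
#' @return List of class `cap_cnt_fit`: `slope`, `intercept`,
#'   `n_points`, `window` and a data frame `curve` with `ln_sigma`,
#'   `ln_J`, `ln_J_fit`, `ln_J_cnt`.
#' @export
cnt_consistency_fit <- function(trajectory, window, T_K = 310,
                                params = cnt_parameters(),
                                normalize_area = TRUE) {
  stopifnot(inherits(trajectory, "cap_trajectory"), length(window) == 2)
  sel <- trajectory$S_ocp >= min(window) & trajectory$S_ocp <= max(window) &
    trajectory$J_ocp > 0
  if (sum(sel) < 3)
    stop("fewer than 3 trajectory points in the supersaturation window",
         call. = FALSE)
  ln_sigma <- log(abs(trajectory$sigma_ocp[sel]))
  J <- trajectory$J_ocp[sel]
  if (normalize_area) J <- J / trajectory$s2_m2[sel]
  ln_J <- log(J)
  fit <- stats::lm(ln_J ~ ln_sigma)
  ln_J_cnt <- log(pmax(nucleation_rate(trajectory$S_ocp[sel], T_K, params),
                       .Machine$double.xmin))
  ln_J_cnt <- ln_J_cnt - mean(ln_J_cnt) + mean(ln_J)   # absorb B
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n_points = sum(sel), window = sort(window),
    curve = data.frame(ln_sigma = ln_sigma, ln_J = ln_J,
                       ln_J_fit = stats::fitted(fit), ln_J_cnt = ln_J_cnt)
  ), class = "cap_cnt_fit")
}
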