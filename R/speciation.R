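# Equilibrium speciation of a physiological medium at fixed pH.
#
# Unknowns are the free Ca2+ and Mg2+ concentrations (log-transformed,
# damped Newton iteration); at given (Ca, Mg) the phosphate, carbonate
# and sulfate sub-systems are linear in their master species and are
# eliminated in closed form, so their mass balances hold to machine
# precision and the Newton residual is the two cation balances. pH is
# read as hydrogen-ion activity (the operational pH-meter definition);
# mass-action expressions use concentrations with the conditional
# constants of the packaged table, and single-ion activities (Davies)
# enter only the ion activity products.

.species_charge <- c(
  Ca = 2, Mg = 2, HPO4 = 2, H2PO4 = 1, H3PO4 = 0, PO4 = 3,
  HCO3 = 1, CO3 = 2, SO4 = 2, HSO4 = 1
)

# compile an equilibrium table into plain-scalar constants (L/mol scale)
.compile_constants <- function(reactions, phosphate_form) {
  lgK <- .lgK_lookup(reactions)
  K <- function(id) if (is.finite(lgK[[id]])) 10^lgK[[id]] else 0
  list(
    Ka_HSO4 = K("HSO4"), Ka1 = K("H3PO4"), Ka2 = K("H2PO4"),
    Ka3 = K("HPO4"), KaC = K("HCO3"),
    CaHPO4 = K("CaHPO4"), CaH2PO4 = K("CaH2PO4"), CaSO4 = K("CaSO4"),
    CaHCO3 = K("CaHCO3"), CaCO3 = K("CaCO3"),
    MgHPO4 = K("MgHPO4"), MgH2PO4 = K("MgH2PO4"), MgSO4 = K("MgSO4"),
    MgHCO3 = K("MgHCO3"), MgCO3 = K("MgCO3"),
    K_alb = c(K("CaBSA1"), K("CaBSA2"), K("CaBSA3")),
    p_master = phosphate_form
  )
}

# ladder ratios of derived species relative to the master species, at
# hydrogen-ion concentration H (mol/L); a zero dissociation constant
# marks the corresponding species as absent
.ladder_ratios <- function(cst, H) {
  if (cst$p_master == "HPO4") {
    r_HPO4 <- 1
    r_H2PO4 <- if (cst$Ka2 > 0) H / cst$Ka2 else 0
    r_H3PO4 <- if (cst$Ka1 > 0 && r_H2PO4 > 0) r_H2PO4 * H / cst$Ka1 else 0
    r_PO4 <- cst$Ka3 / H
  } else {
    r_H2PO4 <- 1
    r_HPO4 <- cst$Ka2 / H
    r_H3PO4 <- if (cst$Ka1 > 0) H / cst$Ka1 else 0
    r_PO4 <- r_HPO4 * cst$Ka3 / H
  }
  list(
    H3PO4 = r_H3PO4, H2PO4 = r_H2PO4, HPO4 = r_HPO4, PO4 = r_PO4,
    HCO3 = 1, CO3 = cst$KaC / H,
    SO4 = 1, HSO4 = if (cst$Ka_HSO4 > 0) H / cst$Ka_HSO4 else 0
  )
}

# core solver. Totals in mol/L; H = hydrogen-ion concentration (mol/L);
# albM = total albumin (mol/L). Returns free/complex concentrations in
# mol/L plus convergence diagnostics. 'start' optionally warm-starts
# the Newton iteration with c(Ca, Mg) free concentrations.
.spec_core <- function(CaT, MgT, PT, CT, ST, H, cst, albM = 0,
                       start = NULL, tol = 1e-13, max_iter = 200) {
  CaT <- unname(CaT); MgT <- unname(MgT); PT <- unname(PT)
  CT <- unname(CT); ST <- unname(ST); H <- unname(H)
  if (!is.null(start)) start <- unname(start)
  r <- .ladder_ratios(cst, H)

  side_factors <- function(Ca, Mg) {
    fP <- r$H3PO4 + r$H2PO4 + r$HPO4 + r$PO4 +
      Ca * (cst$CaHPO4 * r$HPO4 + cst$CaH2PO4 * r$H2PO4) +
      Mg * (cst$MgHPO4 * r$HPO4 + cst$MgH2PO4 * r$H2PO4)
    fC <- 1 + r$CO3 +
      Ca * (cst$CaHCO3 + cst$CaCO3 * r$CO3) +
      Mg * (cst$MgHCO3 + cst$MgCO3 * r$CO3)
    fS <- 1 + r$HSO4 + Ca * cst$CaSO4 + Mg * cst$MgSO4
    c(P = PT / fP, C = CT / fC, S = ST / fS)   # masters
  }

  alb_bound <- function(Ca) {
    if (albM <= 0) return(0)
    albM * sum(cst$K_alb * Ca / (1 + cst$K_alb * Ca))
  }

  residual <- function(Ca, Mg) {
    m <- side_factors(Ca, Mg)
    HPO4 <- m[[1]] * r$HPO4; H2PO4 <- m[[1]] * r$H2PO4
    HCO3 <- m[[2]]; CO3 <- m[[2]] * r$CO3; SO4 <- m[[3]]
    rCa <- Ca * (1 + cst$CaHPO4 * HPO4 + cst$CaH2PO4 * H2PO4 +
                   cst$CaSO4 * SO4 + cst$CaHCO3 * HCO3 +
                   cst$CaCO3 * CO3) + alb_bound(Ca) - CaT
    rMg <- Mg * (1 + cst$MgHPO4 * HPO4 + cst$MgH2PO4 * H2PO4 +
                   cst$MgSO4 * SO4 + cst$MgHCO3 * HCO3 +
                   cst$MgCO3 * CO3) - MgT
    c(rCa, rMg)
  }

  # degenerate pools solve trivially
  solveCa <- CaT > 0; solveMg <- MgT > 0
  Ca <- if (solveCa) CaT else 0
  Mg <- if (solveMg) MgT else 0
  if (!is.null(start)) {
    if (solveCa && start[1] > 0) Ca <- start[1]
    if (solveMg && start[2] > 0) Mg <- start[2]
  }

  iter <- 0L; worst <- Inf
  if (solveCa || solveMg) {
    lx <- log(c(Ca, Mg)[c(solveCa, solveMg)])
    unpack <- function(lx) {
      v <- exp(lx); i <- 1L
      if (solveCa) { Ca <<- v[i]; i <- i + 1L }
      if (solveMg) Mg <<- v[i]
    }
    res_l <- function(lx) { unpack(lx); residual(Ca, Mg)[c(solveCa, solveMg)] }
    n <- length(lx)
    repeat {
      iter <- iter + 1L
      rv <- res_l(lx); worst <- max(abs(rv))
      if (worst < tol || iter > max_iter) break
      J <- matrix(0, n, n); h <- 1e-7
      for (j in seq_len(n)) {
        lp <- lx; lp[j] <- lp[j] + h
        J[, j] <- (res_l(lp) - rv) / h
      }
      step <- tryCatch(solve(J, -rv), error = function(e) -rv)
      step <- pmax(pmin(step, 5), -5)     # trust region in log space
      lam <- 1
      repeat {
        rn <- res_l(lx + lam * step)
        if (max(abs(rn)) < worst || lam < 1e-8) break
        lam <- lam / 2
      }
      lx <- lx + lam * step
    }
    unpack(lx)
  } else worst <- 0

  m <- side_factors(Ca, Mg)
  mP <- m[[1]]; mC <- m[[2]]; mS <- m[[3]]
  free <- c(
    Ca = Ca, Mg = Mg,
    H3PO4 = mP * r$H3PO4, H2PO4 = mP * r$H2PO4,
    HPO4 = mP * r$HPO4, PO4 = mP * r$PO4,
    HCO3 = mC, CO3 = mC * r$CO3,
    SO4 = mS, HSO4 = mS * r$HSO4
  )
  complexes <- c(
    CaHPO4 = cst$CaHPO4 * Ca * free[["HPO4"]],
    CaH2PO4 = cst$CaH2PO4 * Ca * free[["H2PO4"]],
    CaSO4 = cst$CaSO4 * Ca * free[["SO4"]],
    CaHCO3 = cst$CaHCO3 * Ca * free[["HCO3"]],
    CaCO3 = cst$CaCO3 * Ca * free[["CO3"]],
    MgHPO4 = cst$MgHPO4 * Mg * free[["HPO4"]],
    MgH2PO4 = cst$MgH2PO4 * Mg * free[["H2PO4"]],
    MgSO4 = cst$MgSO4 * Mg * free[["SO4"]],
    MgHCO3 = cst$MgHCO3 * Mg * free[["HCO3"]],
    MgCO3 = cst$MgCO3 * Mg * free[["CO3"]],
    CaAlbumin = alb_bound(Ca)
  )
  resid5 <- c(
    Ca = sum(free[["Ca"]], complexes[c("CaHPO4", "CaH2PO4", "CaSO4",
                                       "CaHCO3", "CaCO3", "CaAlbumin")]) - CaT,
    Mg = sum(free[["Mg"]], complexes[c("MgHPO4", "MgH2PO4", "MgSO4",
                                       "MgHCO3", "MgCO3")]) - MgT,
    P = sum(free[c("H3PO4", "H2PO4", "HPO4", "PO4")],
            complexes[c("CaHPO4", "CaH2PO4", "MgHPO4", "MgH2PO4")]) - PT,
    CO3 = sum(free[c("HCO3", "CO3")],
              complexes[c("CaHCO3", "CaCO3", "MgHCO3", "MgCO3")]) - CT,
    SO4 = sum(free[c("SO4", "HSO4")],
              complexes[c("CaSO4", "MgSO4")]) - ST
  )
  list(free = free, complexes = complexes, residuals = resid5,
       converged = worst < tol, iterations = iter, worst = worst)
}

#' Solve the equilibrium ion speciation of a medium
#'
#' Distributes the analytical totals of a [medium()] over free ions,
#' acid-base forms and Ca/Mg ion pairs at the medium's fixed pH, adding
#' the three-site Scatchard calcium-albumin term when albumin is
#' present. Mass balances for Ca, Mg, total phosphate, total carbonate
#' and total sulfate are satisfied simultaneously; the ionic strength is
#' computed once from the analytical totals and is not iterated with the
#' speciation.
#'
#' @param med A [medium()].
#' @param reactions Equilibrium table as from [default_equilibria()].
#' @param phases List of [phase()] objects for which saturation ratios
#'   are evaluated (default DCPD and OCP).
#' @param model An [activity_model()].
#' @param tol Convergence tolerance on the mass-balance residuals, in mM.
#' @param max_iter Newton iteration cap.
#' @param warn_davies Warn when the ionic strength is outside the
#'   Davies validity range.
#' @return An object of class `cap_speciation`: free and complexed
#'   concentrations (mM), activity coefficients per charge, single-ion
#'   activities (mol/L), ionic strength (M), the calcium fraction bound
#'   to albumin, mass-balance residuals (mM) and a `saturation` data
#'   frame with S and sigma = 1 - S per phase.
#' @examples
#' sp <- speciate(sbf_medium())
#' sp$saturation
#' @export
speciate <- function(med, reactions = default_equilibria(),
                     phases = list(dcpd_phase(), ocp_phase()),
                     model = activity_model(), tol = 1e-10,
                     max_iter = 200, warn_davies = TRUE) {
  stopifnot(inherits(med, "cap_medium"))
  I <- medium_ionic_strength(med)
  lg <- davies_log_gamma(0:3, I, model, warn = warn_davies)
  gamma <- stats::setNames(10^lg, as.character(0:3))
  H <- 10^(-med$pH) / gamma[["1"]]   # pH read as activity
  cst <- .compile_constants(reactions, med$phosphate_form)
  tot <- med$totals / 1000
  PT <- tot[[med$phosphate_form]]
  core <- .spec_core(tot[["Ca"]], tot[["Mg"]], PT, tot[["HCO3"]],
                     tot[["SO4"]], H, cst,
                     albM = med$albumin_g_per_L / med$albumin_molar_mass,
                     tol = tol / 1000, max_iter = max_iter)
  if (!core$converged)
    stop(sprintf(
      "speciation did not converge in %d iterations (worst residual %.3g mM)",
      max_iter, core$worst * 1000), call. = FALSE)
  act <- core$free * gamma[as.character(.species_charge[names(core$free)])]
  act <- c(act, H = 10^(-med$pH))
  ca_bound <- if (tot[["Ca"]] > 0)
    core$complexes[["CaAlbumin"]] / tot[["Ca"]] else 0
  out <- structure(list(
    free = core$free * 1000,
    complexes = core$complexes * 1000,
    gamma = gamma,
    activities = act,
    ionic_strength = I,
    ca_bound_to_albumin_fraction = ca_bound,
    mass_balance_residuals = core$residuals * 1000,
    pH = med$pH, medium = med,
    converged = core$converged, iterations = core$iterations
  ), class = "cap_speciation")
  out$saturation <- do.call(rbind, lapply(phases, function(ph) {
    s <- saturation(out, ph)
    data.frame(phase = ph$name, S = s[["S"]], sigma = s[["sigma"]])
  }))
  out
}

#' @export
print.cap_speciation <- function(x, digits = 4, ...) {
  cat("Speciation at pH", format(x$pH),
      "; I =", format(round(x$ionic_strength, 4)), "M\n")
  cat("Free species (mM):\n")
  print(round(x$free, digits))
  if (x$ca_bound_to_albumin_fraction > 0)
    cat("Ca bound to albumin:",
        format(round(100 * x$ca_bound_to_albumin_fraction, 2)), "mol %\n")
  if (!is.null(x$saturation)) {
    cat("Saturation ratios:\n")
    print(x$saturation, row.names = FALSE)
  }
  invisible(x)
}

#' Mineral phase definition
#'
#' A sparingly soluble phase described by its ion activity product: a
#' named exponent vector over solution-species activities, the solubility
#' product the IAP is compared against, and the number of ion units used
#' in the 1/n root of the saturation ratio.
#'
#' @param name Phase label.
#' @param Ksp Solubility product at 37 degC (activity scale).
#' @param iap Named numeric vector of IAP exponents (names must be
#'   species with activities in a `cap_speciation`, e.g. `Ca`, `HPO4`,
#'   `PO4`, `H`).
#' @param n_ion_units Ion count n for `S = (IAP/Ksp)^(1/n)`; must equal
#'   the sum of the IAP exponents.
#' @param molar_mass g/mol.
#' @param molar_volume m^3/mol (optional; used by the nucleation module).
#' @return An object of class `cap_phase`.
#' @export
phase <- function(name, Ksp, iap, n_ion_units, molar_mass,
                  molar_volume = NA_real_) {
  stopifnot(Ksp > 0, molar_mass > 0, length(iap) >= 1)
  if (!isTRUE(all.equal(sum(iap), n_ion_units)))
    stop("n_ion_units must equal the sum of the IAP exponents", call. = FALSE)
  structure(list(name = name, Ksp = Ksp, iap = iap,
                 n_ion_units = n_ion_units, molar_mass = molar_mass,
                 molar_volume = molar_volume), class = "cap_phase")
}

#' Brushite (DCPD) phase
#'
#' CaHPO4.2H2O with IAP = a(Ca2+) a(HPO4 2-), Ksp = 2.2e-7 at 37 degC,
#' n = 2 ion units, molar mass 172.09 g/mol.
#' @return A `cap_phase`.
#' @export
dcpd_phase <- function() {
  phase("DCPD", Ksp = 2.2e-7, iap = c(Ca = 1, HPO4 = 1), n_ion_units = 2,
        molar_mass = 172.09, molar_volume = 172.09 / 2.33 * 1e-6)
}

#' Octacalcium phosphate (OCP) phase
#'
#' Ca8(HPO4)2(PO4)4.5H2O. The solubility product 2.5e-99 at 37 degC is
#' defined on the hydrogen convention, i.e. for the dissociation
#' Ca8H2(PO4)6 -> 8 Ca2+ + 2 H+ + 6 PO4 3- (the square of the
#' conventional half-formula Ca4H(PO4)3 product), so the IAP is
#' a(Ca)^8 a(H)^2 a(PO4)^6 with n = 16 ion units. Molar volume from the
#' unit cell volume 1220 A^3 with Z = 2.
#' @return A `cap_phase`.
#' @export
ocp_phase <- function() {
  phase("OCP", Ksp = 2.5e-99, iap = c(Ca = 8, H = 2, PO4 = 6),
        n_ion_units = 16, molar_mass = 982.6,
        molar_volume = 1220e-30 * 6.02214076e23 / 2)
}

#' Saturation ratio and relative undersaturation of a phase
#'
#' `S = (IAP / Ksp)^(1/n)` with the phase's ion activity product, and
#' `sigma = 1 - S`. `S < 1` drives dissolution, `S > 1` precipitation.
#'
#' @param result A `cap_speciation`.
#' @param ph A [phase()].
#' @return Named vector `c(S = , sigma = )`.
#' @export
saturation <- function(result, ph) {
  stopifnot(inherits(result, "cap_speciation"), inherits(ph, "cap_phase"))
  missing <- setdiff(names(ph$iap), names(result$activities))
  if (length(missing))
    stop("no activity available for species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  a <- result$activities[names(ph$iap)]
  S <- exp((sum(ph$iap * log(a)) - log(ph$Ksp)) / ph$n_ion_units)
  c(S = S, sigma = 1 - S)
}
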