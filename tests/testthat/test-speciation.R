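test_that("with no reactions, free concentrations equal the totals", {
  none <- data.frame(id = character(), equation = character(),
                     lgK = numeric())
  sp <- speciate(sbf_medium(), reactions = none)
  tot <- sbf_medium()$totals
  expect_equal(sp$free[["Ca"]], tot[["Ca"]])
  expect_equal(sp$free[["Mg"]], tot[["Mg"]])
  expect_equal(sp$free[["HPO4"]], tot[["HPO4"]])
  expect_equal(sp$free[["HCO3"]], tot[["HCO3"]])
  expect_equal(sp$free[["SO4"]], tot[["SO4"]])
  expect_true(all(sp$complexes == 0))
})

test_that("back-substitution oracle: mass balances close below tolerance", {
  for (sp in list(fx_speciation_sbf(), fx_speciation_dmem_fbs())) {
    # recompute each balance independently from the returned species
    ca <- sp$free[["Ca"]] + sum(sp$complexes[c("CaHPO4", "CaH2PO4",
             "CaSO4", "CaHCO3", "CaCO3", "CaAlbumin")])
    mg <- sp$free[["Mg"]] + sum(sp$complexes[c("MgHPO4", "MgH2PO4",
             "MgSO4", "MgHCO3", "MgCO3")])
    p <- sum(sp$free[c("H3PO4", "H2PO4", "HPO4", "PO4")]) +
      sum(sp$complexes[c("CaHPO4", "CaH2PO4", "MgHPO4", "MgH2PO4")])
    co3 <- sum(sp$free[c("HCO3", "CO3")]) +
      sum(sp$complexes[c("CaHCO3", "CaCO3", "MgHCO3", "MgCO3")])
    tot <- sp$medium$totals
    expect_lt(abs(ca - tot[["Ca"]]), 1e-10)
    expect_lt(abs(mg - tot[["Mg"]]), 1e-10)
    expect_lt(abs(p - tot[[sp$medium$phosphate_form]]), 1e-10)
    expect_lt(abs(co3 - tot[["HCO3"]]), 1e-10)
    expect_true(all(abs(sp$mass_balance_residuals) < 1e-10))
  }
})

test_that("all concentrations are physical and the albumin fraction bounded", {
  sp <- fx_speciation_dmem_fbs()
  expect_true(all(sp$free >= 0))
  expect_true(all(sp$complexes >= 0))
  expect_gte(sp$ca_bound_to_albumin_fraction, 0)
  expect_lte(sp$ca_bound_to_albumin_fraction, 1)
})

test_that("increasing total Ca never decreases the saturation ratios", {
  base <- sbf_medium()
  S <- t(sapply(seq(0.5, 6, by = 0.5), function(ca) {
    tot <- base$totals; tot[["Ca"]] <- ca
    m <- medium(tot, pH = base$pH, buffer = "tris", tris_mM = base$tris_mM)
    sp <- speciate(m, warn_davies = FALSE)
    c(sp$saturation$S[1], sp$saturation$S[2])
  }))
  expect_true(all(diff(S[, 1]) > 0))
  expect_true(all(diff(S[, 2]) > 0))
})

test_that("albumin at zero reproduces the inorganic solution bit-for-bit", {
  plain <- speciate(dmem_medium(0))
  # removing the albumin site reactions entirely must change nothing
  inorganic <- default_equilibria()
  inorganic <- inorganic[!grepl("^CaBSA", inorganic$id), ]
  no_sites <- speciate(dmem_medium(0), reactions = inorganic)
  expect_identical(plain$free, no_sites$free)
  expect_equal(plain$complexes[["CaAlbumin"]], 0)
  expect_equal(plain$ca_bound_to_albumin_fraction, 0)
})

test_that("dilute limit: gamma -> 1 and activities equal concentrations", {
  m <- medium(1e-6 * c(Na = 10, K = 0, Mg = 1, Ca = 1, Cl = 15,
                       HCO3 = 1, HPO4 = 1, SO4 = 0.5),
              pH = 7.4, buffer = "carbonate")
  sp <- speciate(m, warn_davies = FALSE)
  expect_true(all(abs(sp$gamma - 1) < 0.01))
  charged <- setdiff(names(sp$free), "H3PO4")
  expect_equal(unname(sp$activities[charged]),
               unname(sp$free[charged] / 1000), tolerance = 0.01)
})

test_that("saturation: equilibrium gives S = 1 and the IAP is homogeneous", {
  sp <- fx_speciation_sbf()
  # a state constructed to sit exactly at the DCPD solubility product
  eq <- sp
  eq$activities[["Ca"]] <- sqrt(2.2e-7)
  eq$activities[["HPO4"]] <- sqrt(2.2e-7)
  s <- saturation(eq, dcpd_phase())
  expect_equal(unname(s[["S"]]), 1)
  expect_equal(unname(s[["sigma"]]), 0)
  # doubling both activities doubles S_DCPD (exponents sum to n)
  dbl <- sp
  dbl$activities[["Ca"]] <- 2 * dbl$activities[["Ca"]]
  dbl$activities[["HPO4"]] <- 2 * dbl$activities[["HPO4"]]
  expect_equal(unname(saturation(dbl, dcpd_phase())[["S"]]),
               2 * unname(saturation(sp, dcpd_phase())[["S"]]),
               tolerance = 1e-12)
})

test_that("SBF is undersaturated for DCPD and supersaturated for OCP", {
  sat <- fx_speciation_sbf()$saturation
  expect_lt(sat$S[sat$phase == "DCPD"], 1)
  expect_gt(sat$S[sat$phase == "OCP"], 1)
})

test_that("configuration errors are reported", {
  expect_error(phase("X", 1e-5, c(Ca = 1, HPO4 = 2), 2, 100),
               "sum of the IAP exponents")
  bad <- data.frame(id = "CaXYZ", equation = "?", lgK = 1)
  expect_error(speciate(sbf_medium(), reactions = bad), "unknown reaction")
  odd <- phase("odd", 1e-5, c(Xx = 1), 1, 100)
  expect_error(saturation(fx_speciation_sbf(), odd), "no activity")
  expect_error(medium(c(Na = 1), pH = 7), "missing totals")
  expect_error(medium(sbf_medium()$totals, pH = 15), "pH")
})
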