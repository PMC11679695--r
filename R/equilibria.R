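# The association/dissociation reaction network of the model media.
#
# Fifteen solution equilibria (acid-base ladders of phosphate, carbonate
# and sulfate, plus Ca/Mg ion pairs) and the three calcium binding sites
# of serum albumin. The lgK values are conditional constants for
# I = 0.15-0.2 M at 37 degC and are used at face value with
# concentrations; single-ion activities enter only the ion activity
# products of the mineral phases.
#
# One entry deviates from the commonly tabulated source values: the
# CaCO3(aq) ion-pair constant. The tabulated 8.63 is the calcite
# solubility product at 37 degC, not an ion-pair constant; used as an
# association constant it drives essentially all calcium into CaCO3(aq)
# (free Ca ~ 2 umol/L in SBF), contradicting the well-established
# undersaturation of SBF with respect to brushite. The standard
# CaCO3(aq) ion-pair value lgK = 3.22 is used instead (see the methods
# vignette).

.default_lgK <- c(
  HSO4     = -1.94,   # HSO4- = H+ + SO4 2-
  H3PO4    = -2.04,   # H3PO4 = H+ + H2PO4-
  H2PO4    = -6.7,    # H2PO4- = H+ + HPO4 2-
  HPO4     = -11.55,  # HPO4 2- = H+ + PO4 3-
  HCO3     = -10.25,  # HCO3- = H+ + CO3 2-
  CaHPO4   = 1.3,     # Ca2+ + HPO4 2- = CaHPO4 (aq)
  CaH2PO4  = 0.55,    # Ca2+ + H2PO4- = CaH2PO4+
  CaSO4    = 4.43,    # Ca2+ + SO4 2- = CaSO4 (aq)
  CaHCO3   = 1.17,    # Ca2+ + HCO3- = CaHCO3+
  CaCO3    = 3.22,    # Ca2+ + CO3 2- = CaCO3 (aq)  [ion pair; see note]
  MgHPO4   = 1.8,     # Mg2+ + HPO4 2- = MgHPO4 (aq)
  MgH2PO4  = 0.55,    # Mg2+ + H2PO4- = MgH2PO4+
  MgSO4    = 2.37,    # Mg2+ + SO4 2- = MgSO4 (aq)
  MgHCO3   = 0.62,    # Mg2+ + HCO3- = MgHCO3+
  MgCO3    = 1.87,    # Mg2+ + CO3 2- = MgCO3 (aq)
  CaBSA1   = log10(361),  # Ca2+ + BSA site 1
  CaBSA2   = log10(314),  # Ca2+ + BSA site 2
  CaBSA3   = log10(291)   # Ca2+ + BSA site 3
)

.equilibrium_equations <- c(
  HSO4    = "HSO4- = H+ + SO4 2-",
  H3PO4   = "H3PO4 = H+ + H2PO4-",
  H2PO4   = "H2PO4- = H+ + HPO4 2-",
  HPO4    = "HPO4 2- = H+ + PO4 3-",
  HCO3    = "HCO3- = H+ + CO3 2-",
  CaHPO4  = "Ca2+ + HPO4 2- = CaHPO4 (aq)",
  CaH2PO4 = "Ca2+ + H2PO4- = CaH2PO4+",
  CaSO4   = "Ca2+ + SO4 2- = CaSO4 (aq)",
  CaHCO3  = "Ca2+ + HCO3- = CaHCO3+",
  CaCO3   = "Ca2+ + CO3 2- = CaCO3 (aq)",
  MgHPO4  = "Mg2+ + HPO4 2- = MgHPO4 (aq)",
  MgH2PO4 = "Mg2+ + H2PO4- = MgH2PO4+",
  MgSO4   = "Mg2+ + SO4 2- = MgSO4 (aq)",
  MgHCO3  = "Mg2+ + HCO3- = MgHCO3+",
  MgCO3   = "Mg2+ + CO3 2- = MgCO3 (aq)",
  CaBSA1  = "Ca2+ + BSA1 = CaBSA1",
  CaBSA2  = "Ca2+ + BSA2 = CaBSA2",
  CaBSA3  = "Ca2+ + BSA3 = CaBSA3"
)

#' Default equilibrium-constant table
#'
#' The 15 association/dissociation reactions of the inorganic network
#' plus the three calcium-albumin site constants, as a data frame with
#' columns `id`, `equation` and `lgK` (log10 constants at 37 degC,
#' conditional for I = 0.15-0.2 M). The table can be edited (or loaded
#' from CSV via [read_equilibria()]) and passed to [speciate()];
#' reaction ids are fixed, lgK values are overridable.
#'
#' @return A data frame with one row per reaction.
#' @export
default_equilibria <- function() {
  data.frame(
    id = names(.default_lgK),
    equation = unname(.equilibrium_equations[names(.default_lgK)]),
    lgK = unname(.default_lgK),
    stringsAsFactors = FALSE
  )
}

#' Read an equilibrium table from CSV
#'
#' @param path CSV file with columns `id`, `equation` (optional), `lgK`.
#' @return A data frame accepted by [speciate()].
#' @export
read_equilibria <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "lgK") %in% names(df)))
    stop("equilibrium table needs columns 'id' and 'lgK'", call. = FALSE)
  if (!"equation" %in% names(df))
    df$equation <- unname(.equilibrium_equations[df$id])
  validate_equilibria(df)
  df[c("id", "equation", "lgK")]
}

validate_equilibria <- function(df) {
  unknown <- setdiff(df$id, names(.default_lgK))
  if (length(unknown))
    stop("unknown reaction id(s) in equilibrium table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicated reaction id(s) in equilibrium table", call. = FALSE)
  invisible(df)
}

# assemble the constant list used by the solver; reactions absent from
# the table get K = 0 (association) / act as absent species
.lgK_lookup <- function(reactions) {
  validate_equilibria(reactions)
  lgK <- stats::setNames(rep(-Inf, length(.default_lgK)), names(.default_lgK))
  lgK[reactions$id] <- reactions$lgK
  # dissociation constants: -Inf means the protonated form is absent
  lgK
}
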